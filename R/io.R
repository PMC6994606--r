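#' Read a single-cell count matrix
#'
#' Reads raw UMI counts from a 10x Genomics-style MTX triplet (matrix.mtx +
#' genes/features.tsv + barcodes.tsv) or from a dense CSV/TSV with a header
#' row and a leading name column. Whatever the on-disk orientation, the
#' returned matrix is stored cells x genes.
#'
#' Duplicate gene names are deduplicated by suffixing `.1`, `.2`, ... to
#' repeated occurrences, with a warning.
#'
#' @param path path to the MTX directory, or to the CSV/TSV file.
#' @param format `"mtx_dir"`, `"csv"` or `"tsv"`.
#' @param orientation orientation of the file: `"genes_by_cells"` (the 10x
#'   convention, default) or `"cells_by_genes"`. Ignored for MTX, which is
#'   always genes x cells.
#' @return An [ExpressionMatrix] with `stage = "raw"`.
#' @export
read_counts <- function(path, format = c("mtx_dir", "csv", "tsv"),
                        orientation = c("genes_by_cells", "cells_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path))
  if (format == "mtx_dir") {
    m <- .read_mtx_dir(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    # row names are read manually: duplicate gene names must survive until
    # dedup_names, and read.table(row.names=) would reject them
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    if (orientation == "genes_by_cells") m <- t(m)
  }
  if (any(m < 0)) stop("count matrix contains negative entries")
  if (any(m != round(m))) stop("count matrix contains non-integer entries")
  colnames(m) <- dedup_names(colnames(m), "gene")
  ExpressionMatrix(m, stage = "raw")
}

.read_mtx_dir <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("not a directory: %s", dir))
  mtx <- .find_one(dir, c("matrix.mtx", "matrix.mtx.gz"), "matrix")
  feat <- .find_one(dir, c("features.tsv", "genes.tsv", "features.tsv.gz",
                           "genes.tsv.gz"), "features/genes")
  bcs <- .find_one(dir, c("barcodes.tsv", "barcodes.tsv.gz"), "barcodes")
  mm <- tryCatch(Matrix::readMM(mtx),
                 error = function(e) stop(sprintf(
                   "malformed MatrixMarket file %s: %s", mtx, conditionMessage(e))))
  genes <- utils::read.table(feat, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.table(bcs, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  # 10x features files carry (id, symbol, ...); use the symbol column if present
  gene_names <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
  if (nrow(mm) != length(gene_names))
    stop(sprintf("matrix has %d rows but features file lists %d genes",
                 nrow(mm), length(gene_names)))
  if (ncol(mm) != length(barcodes))
    stop(sprintf("matrix has %d columns but barcodes file lists %d cells",
                 ncol(mm), length(barcodes)))
  m <- t(as.matrix(mm))                      # MTX is genes x cells
  dimnames(m) <- list(barcodes, gene_names)
  m
}

.find_one <- function(dir, candidates, what) {
  hits <- file.path(dir, candidates)
  hits <- hits[file.exists(hits)]
  if (!length(hits)) stop(sprintf("no %s file found in %s", what, dir))
  hits[1]
}

#' Deduplicate feature names by suffixing
#'
#' Repeated names keep the first occurrence unchanged and suffix later ones
#' with `.1`, `.2`, ...
#' @param x character vector of names.
#' @param what label used in the warning message.
#' @return character vector of unique names.
#' @export
dedup_names <- function(x, what = "feature") {
  if (!anyDuplicated(x)) return(x)
  n_dup <- sum(duplicated(x))
  out <- x
  for (nm in unique(x[duplicated(x)])) {
    idx <- which(x == nm)
    out[idx[-1]] <- paste0(nm, ".", seq_along(idx[-1]))
  }
  warning(sprintf("%d duplicate %s names deduplicated by suffixing", n_dup, what))
  out
}

#' Read an ADT count matrix
#'
#' ADT (antibody-derived tag) counts as CSV/TSV, proteins x cells on disk by
#' convention; returned cells x proteins.
#'
#' @param path path to the CSV/TSV file.
#' @param format `"csv"` or `"tsv"`.
#' @param orientation on-disk orientation, default `"proteins_by_cells"`.
#' @return A [ProteinMatrix] with `stage = "counts"`.
#' @export
read_adt <- function(path, format = c("csv", "tsv"),
                     orientation = c("proteins_by_cells", "cells_by_proteins")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path))
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (orientation == "proteins_by_cells") m <- t(m)
  ProteinMatrix(m, stage = "counts")
}

#' Read cell-type labels
#'
#' Two-column CSV: barcode, cell-type label (header optional but recommended).
#'
#' @param path path to the CSV file.
#' @return A [CellLabels] object.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path))
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("labels file must have two columns: barcode, label")
  CellLabels(tab[[1]], tab[[2]])
}

#' Write a matrix container to gzip CSV
#'
#' Writes cells x features with 6 significant digits; a leading comment line
#' records the orientation.
#'
#' @param x an [ExpressionMatrix] or [ProteinMatrix].
#' @param path output path; `.gz` suffix triggers gzip.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  v <- signif(x$values, 6)
  writeLines(sprintf("# orientation: cells_by_features; stage: %s", x$stage), con)
  writeLines(paste(c("barcode", colnames(v)), collapse = ","), con)
  utils::write.table(data.frame(barcode = rownames(v), v, check.names = FALSE),
                     con, sep = ",", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
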