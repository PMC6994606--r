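#' Single-cell expression and protein containers
#'
#' `ExpressionMatrix` holds non-negative gene expression values (raw UMI
#' counts, denoised counts, or log-normalized values) for a set of cells.
#' `ProteinMatrix` holds antibody-derived-tag (ADT) values, either raw counts
#' or centered log-ratio (CLR) relative abundances. Both are stored internally
#' as dense cells-by-features matrices with barcodes on rows and feature names
#' on columns, whatever the orientation of the input file; a `stage` tag
#' records which transform (if any) produced the values.
#'
#' @param values numeric matrix, cells in rows and features in columns.
#' @param gene_names,protein_names character vector of unique feature names;
#'   defaults to `colnames(values)`.
#' @param cell_barcodes character vector of unique cell barcodes; defaults to
#'   `rownames(values)`.
#' @param stage processing stage: one of `"raw"`, `"denoised"`, `"normalized"`
#'   for expression; `"counts"`, `"clr"` for protein.
#'
#' @return An object of class `ExpressionMatrix` or `ProteinMatrix`: a list
#'   with elements `values` (the matrix) and `stage`.
#'
#' @examples
#' m <- matrix(rpois(6, 3), 2, 3,
#'             dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
#' expr <- ExpressionMatrix(m)
#' n_cells(expr)
#' @export
ExpressionMatrix <- function(values, gene_names = colnames(values),
                             cell_barcodes = rownames(values),
                             stage = c("raw", "denoised", "normalized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_names) || is.null(cell_barcodes))
    stop("gene_names and cell_barcodes are required (or set as dimnames)")
  .check_names(gene_names, ncol(values), "gene_names")
  .check_names(cell_barcodes, nrow(values), "cell_barcodes")
  if (anyNA(values)) stop("expression values contain NA")
  if (stage != "normalized" && any(values < 0))
    stop("expression values must be non-negative")
  dimnames(values) <- list(cell_barcodes, gene_names)
  structure(list(values = values, stage = stage), class = "ExpressionMatrix")
}

#' @rdname ExpressionMatrix
#' @export
ProteinMatrix <- function(values, protein_names = colnames(values),
                          cell_barcodes = rownames(values),
                          stage = c("counts", "clr")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(protein_names) || is.null(cell_barcodes))
    stop("protein_names and cell_barcodes are required (or set as dimnames)")
  .check_names(protein_names, ncol(values), "protein_names")
  .check_names(cell_barcodes, nrow(values), "cell_barcodes")
  if (anyNA(values)) stop("protein values contain NA")
  if (stage == "counts") {
    if (any(values < 0)) stop("ADT counts must be non-negative")
    if (any(values != round(values))) stop("ADT counts must be integers")
  } else {
    rs <- rowSums(values)
    if (any(abs(rs) > 1e-8 * pmax(1, ncol(values))))
      stop("CLR values must sum to 0 within each cell")
  }
  dimnames(values) <- list(cell_barcodes, protein_names)
  structure(list(values = values, stage = stage), class = "ProteinMatrix")
}

.check_names <- function(x, n, what) {
  if (length(x) != n) stop(sprintf("%s has length %d, expected %d",
                                   what, length(x), n))
  if (anyDuplicated(x)) stop(sprintf("%s contains duplicates", what))
  if (any(!nzchar(x))) stop(sprintf("%s contains empty strings", what))
  invisible(TRUE)
}

#' @rdname ExpressionMatrix
#' @param x an `ExpressionMatrix` or `ProteinMatrix`.
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname ExpressionMatrix
#' @export
n_features <- function(x) ncol(x$values)

#' @rdname ExpressionMatrix
#' @export
feature_names <- function(x) colnames(x$values)

#' @rdname ExpressionMatrix
#' @export
cell_barcodes <- function(x) rownames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
print.ProteinMatrix <- function(x, ...) {
  cat(sprintf("ProteinMatrix: %d cells x %d proteins [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  ExpressionMatrix(x$values[i, j, drop = FALSE], stage = x$stage)
}

#' @export
`[.ProteinMatrix` <- function(x, i, j, ...) {
  ProteinMatrix(x$values[i, j, drop = FALSE], stage = x$stage)
}

#' Cell-type labels
#'
#' A named character vector mapping cell barcodes to cell-type labels, used
#' for stratified holdout splits, leave-one-cell-type-out benchmarking and
#' within-cell-type reporting.
#'
#' @param barcodes character vector of cell barcodes.
#' @param types character vector of cell-type labels, same length.
#' @return A `CellLabels` object: named character vector (names = barcodes).
#' @examples
#' CellLabels(c("c1", "c2"), c("T", "B"))
#' @export
CellLabels <- function(barcodes, types) {
  barcodes <- as.character(barcodes)
  types <- as.character(types)
  if (length(barcodes) != length(types))
    stop("barcodes and types must have the same length")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in labels")
  if (anyNA(types) || any(!nzchar(types)))
    stop("every barcode must map to a non-empty label")
  structure(stats::setNames(types, barcodes), class = "CellLabels")
}

#' @export
print.CellLabels <- function(x, ...) {
  tab <- table(unclass(x))
  cat(sprintf("CellLabels: %d cells, %d types\n", length(x), length(tab)))
  print(tab)
  invisible(x)
}

#' @export
`[.CellLabels` <- function(x, i, ...) {
  y <- unclass(x)[i]
  CellLabels(names(y), y)
}

#' Look up labels for a set of barcodes
#'
#' @param labels a `CellLabels` object.
#' @param barcodes barcodes to look up; all must be present.
#' @return character vector of types in the order of `barcodes`.
#' @export
labels_for <- function(labels, barcodes) {
  miss <- setdiff(barcodes, names(labels))
  if (length(miss))
    stop(sprintf("%d barcodes have no cell-type label (e.g. %s)",
                 length(miss), miss[1]))
  unname(unclass(labels)[barcodes])
}
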