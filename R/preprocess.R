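#' Quality-control filtering of a raw count matrix
#'
#' Removes low-quality genes (fewer than `min_gene_count` total counts across
#' cells) and low-quality cells (fewer than `min_genes_per_cell` genes
#' detected). The gene filter is applied first on the full matrix, then the
#' cell filter on the gene-reduced matrix, so a cell's detected-gene count is
#' taken over the genes that survive.
#'
#' @param expr an [ExpressionMatrix] with `stage = "raw"`.
#' @param min_gene_count minimum total count for a gene to be kept (default 10).
#' @param min_genes_per_cell minimum number of detected (count > 0) genes for
#'   a cell to be kept (default 200).
#' @return A filtered [ExpressionMatrix], stage unchanged.
#' @export
qc_filter <- function(expr, min_gene_count = 10, min_genes_per_cell = 200) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$stage != "raw")
    stop("qc_filter expects a raw count matrix")
  v <- expr$values
  keep_genes <- colSums(v) >= min_gene_count
  v <- v[, keep_genes, drop = FALSE]
  keep_cells <- rowSums(v > 0) >= min_genes_per_cell
  if (!any(keep_cells))
    stop("qc_filter removed all cells; lower min_genes_per_cell?")
  if (!any(keep_genes))
    stop("qc_filter removed all genes; lower min_gene_count?")
  v <- v[keep_cells, , drop = FALSE]
  ExpressionMatrix(v, stage = expr$stage)
}

#' Library-size log-normalization of expression values
#'
#' Scales each cell's values to a common library size and log-transforms:
#' with `dialect = "log1p"` (the Seurat LogNormalize convention, default)
#' \eqn{X_{ij} = \ln(1 + \Lambda_{ij} \cdot s / m_j)}; with
#' `dialect = "log_eq1"` \eqn{X_{ij} = \ln(\Lambda_{ij} \cdot s / m_j)} with
#' the convention that zero input maps to zero output. Here \eqn{m_j} is the
#' cell's total count and \eqn{s} the scale factor. Natural logarithm in both.
#'
#' @param expr an [ExpressionMatrix] with stage `"raw"` or `"denoised"`.
#' @param scale_factor library-size target, default 10000.
#' @param dialect `"log1p"` or `"log_eq1"` (see above).
#' @return An [ExpressionMatrix] with `stage = "normalized"`.
#' @export
log_normalize <- function(expr, scale_factor = 10000,
                          dialect = c("log1p", "log_eq1")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  dialect <- match.arg(dialect)
  if (expr$stage == "normalized")
    stop("matrix is already normalized")
  stopifnot(scale_factor > 0)
  v <- expr$values
  m <- rowSums(v)
  if (any(m <= 0)) {
    bad <- rownames(v)[which(m <= 0)[1]]
    stop(sprintf("cell %s has zero total count; cannot normalize", bad))
  }
  scaled <- v * (scale_factor / m)           # recycles by row
  if (dialect == "log1p") {
    out <- log1p(scaled)
  } else {
    out <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
    nz <- scaled > 0
    out[nz] <- log(scaled[nz])
  }
  ExpressionMatrix(out, stage = "normalized")
}

#' Centered log-ratio transform of ADT counts
#'
#' For each cell \eqn{c} with ADT count vector \eqn{p_c}, computes
#' \eqn{y_{ic} = \ln\{(p_{ic} + q) / g(p_c + q)\}} where \eqn{g} is the
#' geometric mean over the cell's proteins and \eqn{q} the pseudocount.
#' Each cell's transformed values sum to zero exactly (up to floating
#' tolerance), the defining CLR identity.
#'
#' @param prot a [ProteinMatrix] with `stage = "counts"`, or a bare
#'   non-negative matrix (cells x proteins).
#' @param pseudocount non-negative value added to every count before the
#'   transform (default 1). Must be positive if any count is zero.
#' @return A [ProteinMatrix] with `stage = "clr"`.
#' @export
clr_transform <- function(prot, pseudocount = 1) {
  if (inherits(prot, "ProteinMatrix")) {
    if (prot$stage != "counts")
      stop("clr_transform expects ADT counts")
    v <- prot$values
  } else {
    v <- as.matrix(prot)
    if (any(v < 0)) stop("ADT values must be non-negative")
  }
  stopifnot(pseudocount >= 0)
  v <- v + pseudocount
  if (any(v <= 0))
    stop("zero ADT counts with pseudocount = 0: geometric mean undefined")
  lg <- log(v)
  y <- lg - rowMeans(lg)                     # log(x/geomean) = log x - mean(log x)
  ProteinMatrix(y, stage = "clr")
}

#' Align an expression matrix to a reference gene list
#'
#' Reorders the matrix to exactly the reference gene list: genes present in
#' both are carried over, reference genes missing from the input become
#' all-zero columns, and input genes absent from the reference are dropped.
#' This is how data from a different experiment is brought into the feature
#' space a model was trained on.
#'
#' @param expr an [ExpressionMatrix] (any stage).
#' @param reference_genes character vector of unique gene names, in the order
#'   the model expects.
#' @return The aligned [ExpressionMatrix], with an `alignment` attribute: a
#'   list `(n_matched, n_zero_filled, n_dropped, zero_filled, dropped)`.
#' @export
align_genes <- function(expr, reference_genes) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (anyDuplicated(reference_genes)) stop("reference gene list has duplicates")
  genes <- feature_names(expr)
  matched <- intersect(reference_genes, genes)
  if (!length(matched))
    stop("no genes matched the reference; wrong species or identifier namespace?")
  zero_filled <- setdiff(reference_genes, genes)
  dropped <- setdiff(genes, reference_genes)
  out <- matrix(0, n_cells(expr), length(reference_genes),
                dimnames = list(cell_barcodes(expr), reference_genes))
  out[, matched] <- expr$values[, matched]
  res <- ExpressionMatrix(out, stage = expr$stage)
  attr(res, "alignment") <- list(
    n_matched = length(matched),
    n_zero_filled = length(zero_filled),
    n_dropped = length(dropped),
    zero_filled = zero_filled,
    dropped = dropped)
  res
}
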