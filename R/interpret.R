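#' Permute a set of gene columns across cells
#'
#' Each listed gene has its cell order independently shuffled, breaking any
#' association between that gene and the per-cell protein abundances while
#' preserving the gene's value multiset exactly. Columns outside the set are
#' untouched.
#'
#' The permutations are drawn under `with_seed(seed)`: one `sample.int(n)`
#' per gene, in the order the genes appear in `gs`. This contract is fixed so
#' results are reproducible and independently recomputable.
#'
#' @param X numeric matrix, cells x genes (or [ExpressionMatrix]).
#' @param gs character vector of gene names to permute (subset of columns).
#' @param seed integer seed.
#' @return matrix of the same shape with the listed columns permuted.
#' @export
permute_genes <- function(X, gs, seed = 1L) {
  if (inherits(X, "ExpressionMatrix")) X <- X$values
  X <- as.matrix(X)
  unknown <- setdiff(gs, colnames(X))
  if (length(unknown))
    stop(sprintf("unknown genes in gs: %s", paste(unknown, collapse = ", ")))
  if (!length(gs)) return(X)
  n <- nrow(X)
  with_seed(seed, {
    for (g in gs) X[, g] <- X[sample.int(n), g]
  })
  X
}

# Deterministic per-(epoch, batch) seed derivation; documented part of the
# influence_scores contract. Kept well below 2^31.
.epoch_seed <- function(seed, epoch) seed + 7919L * epoch
.batch_seed <- function(seed, epoch, batch) seed + 7919L * epoch + batch

#' Permutation influence scores of genes on one protein
#'
#' Quantifies how much the model relies on each gene to impute a given
#' protein. Per epoch, the genes are partitioned at random into disjoint
#' batches of `batch_size` (the last batch smaller); for each batch `gs` the
#' expression of those genes is permuted across cells and the increase in
#' prediction error is measured: `delta = |e_orig - e_perm|`, where both
#' errors are the mean L1 deviation between measured and imputed abundances
#' of the target protein. Every gene in the batch is credited with the
#' batch's delta; a gene's final score is its mean delta over epochs.
#'
#' Scoring on all cells highlights genes whose between-cell-type variation
#' drives the prediction (cell-type markers); restricting `cells` to one cell
#' type removes that axis of variation and reveals genes driving within-type
#' heterogeneity.
#'
#' Randomness contract (reproducible and independently replayable): the
#' epoch-`e` partition is `sample(genes)` under seed `seed + 7919 * e`, cut
#' into consecutive blocks of `batch_size`; batch `b` of epoch `e` is
#' permuted by [permute_genes] with seed `seed + 7919 * e + b`.
#'
#' @param model a trained `ctpnet_model`.
#' @param X normalized expression, cells x genes, aligned to the model.
#' @param Y measured CLR abundances containing the target protein.
#' @param protein the protein to score.
#' @param batch_size genes per permutation batch, default 100.
#' @param n_epochs number of epochs, default 500.
#' @param cells optional barcode subset to score on (e.g. one cell type).
#' @param labels,cell_type alternative to `cells`: restrict to the cells of
#'   `cell_type` under `labels`.
#' @param seed integer seed.
#' @return An importance table: data.frame (gene, protein, cell_subset,
#'   delta, n_epochs_sampled) with attributes `batch_size`, `n_epochs`,
#'   `seed`, `e_orig`.
#' @export
influence_scores <- function(model, X, Y, protein, batch_size = 100L,
                             n_epochs = 500L, cells = NULL, labels = NULL,
                             cell_type = NULL, seed = 1L) {
  stopifnot(inherits(model, "ctpnet_model"), batch_size >= 1, n_epochs >= 1)
  if (!protein %in% model$spec$protein_names)
    stop(sprintf("protein '%s' is not in the model", protein))
  if (inherits(X, "ExpressionMatrix")) X <- X$values
  X <- as.matrix(X)
  Ym <- .as_clr_matrix(Y, "Y")
  if (!protein %in% colnames(Ym))
    stop(sprintf("protein '%s' is not in Y", protein))
  subset_label <- "all cells"
  if (!is.null(cell_type)) {
    if (is.null(labels)) stop("cell_type requires labels")
    cells <- rownames(X)[labels_for(labels, rownames(X)) == cell_type]
    subset_label <- cell_type
  } else if (!is.null(cells)) {
    subset_label <- sprintf("%d selected cells", length(cells))
  }
  if (!is.null(cells)) {
    cells <- intersect(rownames(X), cells)
    if (!length(cells)) stop("cell subset is empty after filtering")
    X <- X[cells, , drop = FALSE]
    Ym <- Ym[cells, , drop = FALSE]
  }
  y <- Ym[, protein]
  genes <- colnames(X)
  G <- length(genes)
  e_orig <- mean(abs(y - forward(model, X, proteins = protein)[, 1]))
  delta_sum <- stats::setNames(numeric(G), genes)
  n_sampled <- stats::setNames(integer(G), genes)
  for (e in seq_len(n_epochs)) {
    ord <- with_seed(.epoch_seed(seed, e), sample(genes))
    starts <- seq(1, G, by = batch_size)
    for (b in seq_along(starts)) {
      gs <- ord[starts[b]:min(starts[b] + batch_size - 1, G)]
      Xp <- permute_genes(X, gs, seed = .batch_seed(seed, e, b))
      e_perm <- mean(abs(y - forward(model, Xp, proteins = protein)[, 1]))
      d <- abs(e_orig - e_perm)
      delta_sum[gs] <- delta_sum[gs] + d
      n_sampled[gs] <- n_sampled[gs] + 1L
    }
  }
  out <- data.frame(gene = genes, protein = protein,
                    cell_subset = subset_label,
                    delta = ifelse(n_sampled > 0, delta_sum / pmax(n_sampled, 1L),
                                   NA_real_),
                    n_epochs_sampled = n_sampled, row.names = NULL)
  attr(out, "batch_size") <- as.integer(batch_size)
  attr(out, "n_epochs") <- as.integer(n_epochs)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "e_orig") <- e_orig
  out
}

#' Rank genes by influence score
#'
#' Orders each (protein, cell subset) group by descending mean delta, ties
#' broken lexicographically by gene name so rankings are deterministic.
#'
#' @param table an importance table from [influence_scores] (tables for
#'   several runs may be `rbind`-ed).
#' @param top_k how many genes to keep per group, default 100.
#' @return data.frame (protein, cell_subset, rank, gene, delta).
#' @export
rank_influences <- function(table, top_k = 100L) {
  stopifnot(nrow(table) > 0)
  groups <- split(table, list(table$protein, table$cell_subset), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(-g$delta, g$gene), ]
    g <- utils::head(g, top_k)
    data.frame(protein = g$protein, cell_subset = g$cell_subset,
               rank = seq_len(nrow(g)), gene = g$gene, delta = g$delta,
               row.names = NULL)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
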