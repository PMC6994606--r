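.safe_cor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

.as_clr_matrix <- function(x, what) {
  if (inherits(x, "ProteinMatrix")) {
    if (x$stage != "clr") stop(sprintf("%s must be on the CLR scale", what))
    x$values
  } else as.matrix(x)
}

#' Per-protein correlation between imputed and measured abundances
#'
#' Computes, for each protein shared between the two matrices, the
#' correlation across cells between imputed and measured CLR abundances —
#' overall, and within each cell type when labels are supplied. Barcodes and
#' protein panels are intersected; zero-variance columns are reported as
#' undefined (`NA` with `undefined = TRUE`), never as 0.
#'
#' @param imputed imputed abundances: matrix (cells x proteins) or
#'   [ProteinMatrix] stage `"clr"`.
#' @param measured measured abundances, same forms.
#' @param labels optional [CellLabels] for within-type correlations.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param scheme name recorded in the report (e.g. `"holdout"`).
#' @return An `eval_report`: list with `scheme`, `n_cells`, `overall`
#'   (data.frame protein, n, cor, undefined) and `by_type` (data.frame
#'   protein, cell_type, n, cor, undefined; `NULL` without labels).
#' @export
correlation_report <- function(imputed, measured, labels = NULL,
                               method = c("pearson", "spearman"),
                               scheme = "holdout") {
  method <- match.arg(method)
  imp <- .as_clr_matrix(imputed, "imputed")
  mea <- .as_clr_matrix(measured, "measured")
  if (is.null(rownames(imp)) || is.null(rownames(mea)))
    stop("both matrices need barcode rownames")
  cells <- intersect(rownames(imp), rownames(mea))
  if (!length(cells)) stop("no shared barcodes between imputed and measured")
  prots <- intersect(colnames(imp), colnames(mea))
  if (!length(prots))
    return(structure(list(scheme = scheme, n_cells = 0L,
                          overall = NULL, by_type = NULL,
                          status = "no shared proteins"),
                     class = "eval_report"))
  imp <- imp[cells, prots, drop = FALSE]
  mea <- mea[cells, prots, drop = FALSE]
  overall <- data.frame(
    protein = prots,
    n = length(cells),
    cor = vapply(prots, function(p) .safe_cor(imp[, p], mea[, p], method), 0),
    row.names = NULL)
  overall$undefined <- is.na(overall$cor)
  by_type <- NULL
  if (!is.null(labels)) {
    types <- labels_for(labels, cells)
    rows <- list()
    for (ty in sort(unique(types))) {
      sel <- types == ty
      rows[[ty]] <- data.frame(
        protein = prots, cell_type = ty, n = sum(sel),
        cor = vapply(prots, function(p)
          .safe_cor(imp[sel, p], mea[sel, p], method), 0),
        row.names = NULL)
    }
    by_type <- do.call(rbind, c(rows, make.row.names = FALSE))
    by_type$undefined <- is.na(by_type$cor)
  }
  structure(list(scheme = scheme, n_cells = length(cells),
                 overall = overall, by_type = by_type, status = "ok"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: %d cells, status: %s\n",
              x$scheme, x$n_cells, x$status))
  if (!is.null(x$overall)) {
    cat(sprintf("  mean per-protein cor: %.3f\n",
                mean(x$overall$cor, na.rm = TRUE)))
    print(x$overall, digits = 3)
  }
  invisible(x)
}

#' Raw-RNA baseline correlation per protein
#'
#' The benchmark every imputation must beat: correlate each measured protein
#' with the expression of its corresponding gene(s). For proteins composed of
#' several genes (e.g. multi-chain complexes) the mapped genes' values are
#' summed per cell before correlating. Mapped genes missing from the
#' expression matrix contribute 0 and are reported; a protein with no mapped
#' gene present is undefined with reason `"missing gene"`.
#'
#' @param expr an [ExpressionMatrix] (any stage: raw counts, denoised or
#'   normalized values).
#' @param measured measured protein abundances ([ProteinMatrix] stage
#'   `"clr"` or matrix), cells x proteins.
#' @param map named list: protein name -> character vector of gene names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with columns protein, cor, n_genes_used,
#'   n_genes_missing, undefined, reason.
#' @export
baseline_rna_correlation <- function(expr, measured, map,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  mea <- .as_clr_matrix(measured, "measured")
  bad <- setdiff(names(map), colnames(mea))
  if (length(bad))
    stop(sprintf("mapped proteins not in measured panel: %s",
                 paste(bad, collapse = ", ")))
  cells <- intersect(rownames(expr$values), rownames(mea))
  if (!length(cells)) stop("no shared barcodes between expression and protein data")
  ev <- expr$values[cells, , drop = FALSE]
  out <- lapply(names(map), function(p) {
    genes <- map[[p]]
    present <- intersect(genes, colnames(ev))
    missing <- setdiff(genes, colnames(ev))
    if (!length(present))
      return(data.frame(protein = p, cor = NA_real_, n_genes_used = 0L,
                        n_genes_missing = length(missing), undefined = TRUE,
                        reason = "missing gene"))
    x <- rowSums(ev[, present, drop = FALSE])
    r <- .safe_cor(x, mea[cells, p], method)
    data.frame(protein = p, cor = r, n_genes_used = length(present),
               n_genes_missing = length(missing), undefined = is.na(r),
               reason = if (is.na(r)) "zero variance" else "")
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Leave-one-cell-type-out evaluation
#'
#' Partitions the cells by type; iteratively holds out all cells of one type,
#' trains a model on the remaining types, and predicts the held-out cells. In
#' the end every cell has been predicted exactly once, by a model that never
#' saw its type — probing generalization to unseen cell populations. Each
#' fold reuses `config` with seed `config$seed + fold index`.
#'
#' @param X normalized expression, cells x genes.
#' @param Y CLR protein abundances, cells x proteins.
#' @param labels a [CellLabels] covering every cell.
#' @param spec a [network_spec].
#' @param config a [train_config].
#' @param restrict_report_to optional barcodes: limit the correlation report
#'   to this subset (e.g. the holdout-scheme validation cells, so the two
#'   schemes are compared on the same cells).
#' @return list with `report` (an `eval_report`, scheme
#'   `"out_of_celltype"`), `predictions` (cells x proteins), and `folds`
#'   (data.frame: cell_type, n_test, n_train, seed, training_types).
#' @export
out_of_celltype_eval <- function(X, Y, labels, spec, config = train_config(),
                                 restrict_report_to = NULL) {
  if (inherits(X, "ExpressionMatrix")) {
    if (X$stage != "normalized") stop("X must be normalized")
    X <- X$values
  }
  Ym <- .as_clr_matrix(Y, "Y")
  types <- labels_for(labels, rownames(X))
  utypes <- sort(unique(types))
  if (length(utypes) < 2)
    stop("out-of-cell-type evaluation needs at least 2 cell types")
  big <- table(types) / length(types) > 0.5
  if (any(big))
    warning(sprintf("cell type '%s' comprises >50%% of cells; training set halves",
                    names(which(big))[1]))
  preds <- matrix(NA_real_, nrow(X), ncol(Ym),
                  dimnames = list(rownames(X), colnames(Ym)))
  folds <- data.frame(cell_type = character(0), n_test = integer(0),
                      n_train = integer(0), seed = integer(0),
                      training_types = character(0))
  for (i in seq_along(utypes)) {
    ty <- utypes[i]
    test_idx <- types == ty
    tr_bc <- rownames(X)[!test_idx]
    fold_cfg <- config
    fold_cfg$seed <- config$seed + i
    fit <- train(X[tr_bc, , drop = FALSE], Ym[tr_bc, , drop = FALSE],
                 spec, fold_cfg, labels = labels[tr_bc])
    preds[test_idx, ] <- forward(fit$model, X[test_idx, , drop = FALSE])
    folds[i, ] <- list(ty, sum(test_idx), length(tr_bc), fold_cfg$seed,
                       paste(setdiff(utypes, ty), collapse = ";"))
  }
  stopifnot(!anyNA(preds))
  rep_bc <- if (is.null(restrict_report_to)) rownames(X)
            else intersect(rownames(X), restrict_report_to)
  report <- correlation_report(preds[rep_bc, , drop = FALSE],
                               Ym[rep_bc, , drop = FALSE],
                               labels = labels, scheme = "out_of_celltype")
  list(report = report, predictions = preds, folds = folds)
}

#' Cross-dataset evaluation
#'
#' Scores a trained model on a different experiment: the test counts go
#' through QC filtering, log-normalization and alignment to the model's
#' training gene list (missing genes zero-filled), the model predicts, and
#' the report is restricted to the proteins shared between the model and the
#' test ADT panel.
#'
#' @param model a trained `ctpnet_model`.
#' @param test_counts raw or denoised [ExpressionMatrix] from the test
#'   experiment.
#' @param test_adt [ProteinMatrix] (stage `"counts"` or `"clr"`) from the
#'   test experiment.
#' @param labels optional [CellLabels] for within-type reporting.
#' @param qc apply [qc_filter] to the test counts first (default `TRUE`).
#' @param dialect,pseudocount preprocessing options forwarded to
#'   [log_normalize] and [clr_transform]; use the values the model was
#'   trained with.
#' @param min_genes_per_cell,min_gene_count QC thresholds.
#' @return list with `report` (`eval_report`, scheme `"cross_dataset"`),
#'   `predictions`, and `alignment` (matched / zero-filled / dropped gene
#'   counts).
#' @export
cross_dataset_eval <- function(model, test_counts, test_adt, labels = NULL,
                               qc = TRUE, dialect = "log1p", pseudocount = 1,
                               min_gene_count = 10, min_genes_per_cell = 200) {
  stopifnot(inherits(model, "ctpnet_model"))
  if (is.null(model$gene_names)) stop("model carries no training gene list")
  expr <- test_counts
  if (qc && expr$stage == "raw")
    expr <- qc_filter(expr, min_gene_count, min_genes_per_cell)
  if (expr$stage != "normalized")
    expr <- log_normalize(expr, dialect = dialect)
  aligned <- align_genes(expr, model$gene_names)
  al <- attr(aligned, "alignment")
  frac <- al$n_matched / length(model$gene_names)
  if (frac < 0.5)
    warning(sprintf("only %.0f%% of model genes found in test data", 100 * frac))
  preds <- forward(model, aligned)
  measured <- if (inherits(test_adt, "ProteinMatrix") && test_adt$stage == "counts")
    clr_transform(test_adt, pseudocount) else test_adt
  report <- correlation_report(preds, measured, labels = labels,
                               scheme = "cross_dataset")
  list(report = report, predictions = preds,
       alignment = al[c("n_matched", "n_zero_filled", "n_dropped")])
}
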