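#' Training configuration
#'
#' @param learning_rate Adam step size, default 1e-4.
#' @param max_epochs number of full passes over the training set, default 139.
#' @param minibatch_size cells per minibatch, default 128.
#' @param holdout_fraction fraction of cells held out for model selection,
#'   default 0.10 (the 90/10 scheme).
#' @param seed integer seed controlling initialization, the holdout split and
#'   minibatch shuffling.
#' @param select_best_by_test_error if `TRUE` (default), return the parameters
#'   from the epoch with the lowest holdout loss rather than the last epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 139L,
                         minibatch_size = 128L, holdout_fraction = 0.10,
                         seed = 1L, select_best_by_test_error = TRUE) {
  stopifnot(learning_rate > 0, max_epochs >= 0, minibatch_size >= 1,
            holdout_fraction > 0, holdout_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 minibatch_size = as.integer(minibatch_size),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed),
                 select_best_by_test_error = isTRUE(select_best_by_test_error)),
            class = "train_config")
}

#' Mean L1 (absolute) loss
#'
#' Mean absolute deviation over all (cell, protein) entries. The mean (rather
#' than the sum) makes the loss — and hence learning-rate defaults —
#' invariant to dataset size.
#'
#' @param Y,Yhat numeric matrices of identical shape.
#' @return non-negative scalar.
#' @export
l1_loss <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!identical(dim(Y), dim(Yhat)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(Y), collapse = "x"), paste(dim(Yhat), collapse = "x")))
  mean(abs(Y - Yhat))
}

#' Stratified train/holdout split
#'
#' Randomly assigns roughly `fraction` of the cells to the holdout (test)
#' set, stratified by cell type so each type is represented in both sets
#' whenever its size permits. Per type, the holdout size is
#' `round(fraction * n_type)`, clamped so at least one cell of every type
#' with two or more cells stays on each side; singleton types go to training
#' with a warning. Deterministic given `seed`.
#'
#' @param barcodes character vector of cell barcodes.
#' @param labels optional [CellLabels]; if `NULL` the split is unstratified.
#' @param fraction holdout fraction in (0, 1).
#' @param seed integer seed.
#' @return list with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_holdout <- function(barcodes, labels = NULL, fraction = 0.10, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (length(barcodes) * fraction < 1)
    stop("fraction * n_cells < 1: holdout would be empty")
  types <- if (is.null(labels)) rep("all", length(barcodes))
           else labels_for(labels, barcodes)
  test <- with_seed(seed, {
    out <- character(0)
    for (ty in sort(unique(types))) {
      bc <- barcodes[types == ty]
      n <- length(bc)
      if (n == 1) {
        if (!is.null(labels))
          warning(sprintf("cell type '%s' has a single cell; kept in training", ty))
        next
      }
      k <- min(max(round(fraction * n), 1), n - 1)
      out <- c(out, sample(bc, k))
    }
    out
  })
  list(train = setdiff(barcodes, test), test = test)
}

# ---- Adam optimizer over the nested parameter list ----------------------

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

# In-place-style functional update; params/grads/m/v share one nested shape.
.adam_update <- function(params, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (k in names(p)) {
        r <- step(p[[k]], g[[k]], m[[k]], v[[k]])
        out$p[[k]] <- r$p; out$m[[k]] <- r$m; out$v[[k]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  step(params, grads, state$m, state$v)
}

# Forward + backward for one minibatch; returns loss and gradients with the
# same nested structure as params. Gradient of mean-L1: sign(Yhat - Y)/(n d).
.loss_and_grads <- function(params, X, Y) {
  n <- nrow(X); d <- ncol(Y)
  H1pre <- .add_bias(X %*% params$trunk1$W, params$trunk1$b)
  H1 <- relu(H1pre)
  H2pre <- .add_bias(H1 %*% params$trunk2$W, params$trunk2$b)
  H2 <- relu(H2pre)
  grads <- list(trunk1 = list(W = NULL, b = NULL),
                trunk2 = list(W = NULL, b = NULL), branches = list())
  G_H2 <- matrix(0, n, ncol(H2))
  loss_sum <- 0
  for (j in seq_len(d)) {
    pn <- colnames(Y)[j]
    br <- params$branches[[pn]]
    Apre <- .add_bias(H2 %*% br$hidden$W, br$hidden$b)
    A <- relu(Apre)
    Yhat <- .add_bias(A %*% br$out$W, br$out$b)
    resid <- Yhat - Y[, j, drop = FALSE]
    loss_sum <- loss_sum + sum(abs(resid))
    G_out <- sign(resid) / (n * d)
    G_A <- (G_out %*% t(br$out$W)) * (Apre > 0)
    grads$branches[[pn]] <- list(
      hidden = list(W = crossprod(H2, G_A), b = colSums(G_A)),
      out = list(W = crossprod(A, G_out), b = colSums(G_out)))
    G_H2 <- G_H2 + G_A %*% t(br$hidden$W)
  }
  G2 <- G_H2 * (H2pre > 0)
  grads$trunk2 <- list(W = crossprod(H1, G2), b = colSums(G2))
  G_H1 <- (G2 %*% t(params$trunk2$W)) * (H1pre > 0)
  grads$trunk1 <- list(W = crossprod(X, G_H1), b = colSums(G_H1))
  list(loss = loss_sum / (n * d), grads = grads)
}

#' Fit the network to paired expression and protein data
#'
#' Minimizes the mean L1 deviation between measured and imputed CLR protein
#' abundances by minibatch Adam. A stratified holdout set is split off before
#' training; its loss is recorded every epoch and, when
#' `select_best_by_test_error` is on, the parameters from the best-holdout
#' epoch are returned (early-stopping-style model selection).
#'
#' @param X normalized expression ([ExpressionMatrix] stage `"normalized"` or
#'   matrix), cells x genes.
#' @param Y CLR protein abundances ([ProteinMatrix] stage `"clr"` or matrix),
#'   cells x proteins, row-aligned with `X` by barcode.
#' @param spec a [network_spec]; its `n_genes` and `protein_names` must match
#'   the data.
#' @param config a [train_config].
#' @param labels optional [CellLabels] for stratifying the holdout split.
#' @return A `ctpnet_fit`: list with `model` (a `ctpnet_model` carrying the
#'   training gene list), `log` (data.frame: epoch, train_loss, holdout_loss,
#'   seconds), `selected_epoch`, and `holdout_barcodes`.
#' @export
train <- function(X, Y, spec, config = train_config(), labels = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "train_config"))
  if (inherits(X, "ExpressionMatrix")) {
    if (X$stage != "normalized") stop("X must be normalized (run log_normalize)")
    X <- X$values
  }
  if (inherits(Y, "ProteinMatrix")) {
    if (Y$stage != "clr") stop("Y must be CLR-transformed (run clr_transform)")
    Y <- Y$values
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of cells")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("X and Y barcodes are not row-aligned")
  if (ncol(X) != spec$n_genes)
    stop(sprintf("X has %d genes but spec expects %d", ncol(X), spec$n_genes))
  if (is.null(colnames(Y))) colnames(Y) <- spec$protein_names
  if (!setequal(colnames(Y), spec$protein_names))
    stop("Y proteins do not match spec protein_names")
  Y <- Y[, spec$protein_names, drop = FALSE]
  if (is.null(rownames(X)))
    rownames(X) <- rownames(Y) <- paste0("cell", seq_len(nrow(X)))

  split <- split_holdout(rownames(X), labels, config$holdout_fraction,
                         config$seed)
  Xtr <- X[split$train, , drop = FALSE]; Ytr <- Y[split$train, , drop = FALSE]
  Xte <- X[split$test, , drop = FALSE];  Yte <- Y[split$test, , drop = FALSE]

  model <- build_network(spec, seed = config$seed)
  model$gene_names <- colnames(X)
  params <- model$params

  log_df <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       holdout_loss = numeric(0), seconds = numeric(0))
  if (config$max_epochs == 0) {
    model$params <- params
    return(structure(list(model = model, log = log_df,
                          selected_epoch = NA_integer_,
                          holdout_barcodes = split$test),
                     class = "ctpnet_fit"))
  }

  state <- list(m = .zeros_like(params), v = .zeros_like(params))
  best <- list(loss = Inf, params = params, epoch = NA_integer_)
  t_global <- 0L
  n_tr <- nrow(Xtr)

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      t0 <- proc.time()[3]
      ord <- sample.int(n_tr)
      starts <- seq(1, n_tr, by = config$minibatch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$minibatch_size - 1, n_tr)]
        fb <- .loss_and_grads(params, Xtr[idx, , drop = FALSE],
                              Ytr[idx, , drop = FALSE])
        if (!is.finite(fb$loss))
          stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate",
                       epoch))
        t_global <- t_global + 1L
        upd <- .adam_update(params, fb$grads, state, config$learning_rate,
                            t_global)
        params <- upd$p; state$m <- upd$m; state$v <- upd$v
      }
      model$params <- params
      tr_loss <- l1_loss(Ytr, forward(model, Xtr))
      te_loss <- l1_loss(Yte, forward(model, Xte))
      if (!is.finite(te_loss))
        stop(sprintf("non-finite holdout loss at epoch %d", epoch))
      log_df[epoch, ] <- list(epoch, tr_loss, te_loss, proc.time()[3] - t0)
      if (te_loss < best$loss)
        best <- list(loss = te_loss, params = params, epoch = epoch)
    }
  })

  selected <- if (config$select_best_by_test_error) best$epoch
              else config$max_epochs
  model$params <- if (config$select_best_by_test_error) best$params else params
  structure(list(model = model, log = log_df, selected_epoch = selected,
                 holdout_barcodes = split$test),
            class = "ctpnet_fit")
}

#' @export
print.ctpnet_fit <- function(x, ...) {
  cat(sprintf("ctpnet_fit: %d epochs, selected epoch %s (holdout L1 %.4f)\n",
              nrow(x$log), x$selected_epoch,
              if (nrow(x$log)) min(x$log$holdout_loss) else NA))
  invisible(x)
}

#' Impute proteins for new count data
#'
#' Convenience wrapper running the model's full prediction pipeline on raw or
#' denoised counts: log-normalization, alignment to the model's training gene
#' list, forward evaluation.
#'
#' @param object a trained `ctpnet_model` (with a gene list).
#' @param counts an [ExpressionMatrix] (stage raw/denoised) or an already
#'   normalized one.
#' @param ... unused.
#' @return matrix of imputed abundances, cells x proteins.
#' @export
predict.ctpnet_model <- function(object, counts, ...) {
  if (is.null(object$gene_names))
    stop("model has no training gene list; train it or load a trained model")
  if (!inherits(counts, "ExpressionMatrix"))
    counts <- ExpressionMatrix(as.matrix(counts), stage = "raw")
  norm <- if (counts$stage == "normalized") counts else log_normalize(counts)
  aligned <- align_genes(norm, object$gene_names)
  forward(object, aligned)
}
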