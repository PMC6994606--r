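MODEL_FORMAT_VERSION <- 1L

#' Specify the multiple-branch network architecture
#'
#' The network maps a cell's normalized expression vector (length `n_genes`)
#' to one imputed relative abundance per protein. Two shared ("trunk") layers
#' learn features common to all proteins — the second is the 128-unit
#' bottleneck whose activations summarize cell state — and each protein then
#' has its own branch of one hidden layer feeding a single output node. All
#' layers are fully connected with ReLU activations except the final output,
#' which is linear (identity), so imputed CLR values may be negative.
#'
#' @param n_genes number of input genes D.
#' @param protein_names character vector of proteins to impute (length d).
#' @param trunk_widths widths of the two shared layers, default `c(1000, 128)`.
#' @param branch_width width of each protein branch's hidden layer, default 64.
#' @return A `network_spec` object.
#' @export
network_spec <- function(n_genes, protein_names,
                         trunk_widths = c(1000L, 128L), branch_width = 64L) {
  if (length(n_genes) != 1 || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (!length(protein_names) || anyDuplicated(protein_names))
    stop("protein_names must be a non-empty set of unique names")
  if (length(trunk_widths) != 2 || any(trunk_widths < 1))
    stop("trunk_widths must be two positive integers")
  if (branch_width < 1) stop("branch_width must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 protein_names = as.character(protein_names),
                 trunk_widths = as.integer(trunk_widths),
                 branch_width = as.integer(branch_width)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec: %d genes -> %d -> %d -> [%d x %d proteins] -> 1\n",
              x$n_genes, x$trunk_widths[1], x$trunk_widths[2],
              x$branch_width, length(x$protein_names)))
  invisible(x)
}

# Kaiming-uniform initialization (fan-in, ReLU gain): U(-sqrt(6/fan_in), +);
# biases start at zero. Weight matrices are (fan_in x fan_out) so the forward
# pass is X %*% W + b.
.init_layer <- function(fan_in, fan_out) {
  limit <- sqrt(6 / fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out),
       b = numeric(fan_out))
}

#' Build and initialize a network
#'
#' Creates the weight tensors for a [network_spec] with seeded
#' Kaiming-uniform initialization: the same seed yields bit-identical
#' parameters.
#'
#' @param spec a [network_spec].
#' @param seed integer seed for the initialization.
#' @return A `ctpnet_model`: list with `spec`, `params` (per-layer `W`/`b`),
#'   `gene_names` (`NULL` until trained), and `format_version`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  w <- spec$trunk_widths
  params <- with_seed(seed, {
    p <- list(trunk1 = .init_layer(spec$n_genes, w[1]),
              trunk2 = .init_layer(w[1], w[2]),
              branches = list())
    for (pn in spec$protein_names) {
      p$branches[[pn]] <- list(hidden = .init_layer(w[2], spec$branch_width),
                               out = .init_layer(spec$branch_width, 1L))
    }
    p
  })
  structure(list(spec = spec, params = params, gene_names = NULL,
                 preprocessing = NULL, format_version = MODEL_FORMAT_VERSION),
            class = "ctpnet_model")
}

#' @export
print.ctpnet_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %s trainable parameters; trained gene list: %s\n",
              format(n_params(x), big.mark = ","),
              if (is.null(x$gene_names)) "none" else length(x$gene_names)))
  invisible(x)
}

#' Count trainable parameters
#'
#' For trunk widths \eqn{(h_1, h_2)}, branch width \eqn{h_b}, D genes and d
#' proteins the count is
#' \eqn{(D h_1 + h_1) + (h_1 h_2 + h_2) + d\,(h_2 h_b + h_b + h_b + 1)}.
#'
#' @param model a `ctpnet_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  cnt <- function(l) length(l$W) + length(l$b)
  p <- model$params
  cnt(p$trunk1) + cnt(p$trunk2) +
    sum(vapply(p$branches, function(br) cnt(br$hidden) + cnt(br$out), 0))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

.add_bias <- function(M, b) M + rep(b, each = nrow(M))

.as_input_matrix <- function(X, spec) {
  if (inherits(X, "ExpressionMatrix")) {
    if (X$stage != "normalized")
      stop("input expression must be normalized (run log_normalize)")
    X <- X$values
  }
  X <- as.matrix(X)
  if (ncol(X) != spec$n_genes)
    stop(sprintf(paste0("input has %d genes but the network expects %d; ",
                        "use align_genes with the model's gene list"),
                 ncol(X), spec$n_genes))
  X
}

#' Forward evaluation: impute protein abundances
#'
#' Runs cells through the network. ReLU is applied after both trunk layers
#' and each branch hidden layer; the output node is linear.
#'
#' @param model a `ctpnet_model`.
#' @param X normalized expression, cells x genes ([ExpressionMatrix] with
#'   `stage = "normalized"`, or a bare matrix).
#' @param proteins optional subset of proteins to impute (default all).
#' @return numeric matrix, cells x selected proteins, of imputed relative
#'   abundances (CLR scale; may be negative).
#' @export
forward <- function(model, X, proteins = NULL) {
  stopifnot(inherits(model, "ctpnet_model"))
  X <- .as_input_matrix(X, model$spec)
  if (is.null(proteins)) proteins <- model$spec$protein_names
  unknown <- setdiff(proteins, model$spec$protein_names)
  if (length(unknown))
    stop(sprintf("proteins not in the model: %s", paste(unknown, collapse = ", ")))
  H <- .trunk_forward(model$params, X)
  out <- matrix(NA_real_, nrow(X), length(proteins),
                dimnames = list(rownames(X), proteins))
  for (pn in proteins) {
    br <- model$params$branches[[pn]]
    A <- relu(.add_bias(H %*% br$hidden$W, br$hidden$b))
    out[, pn] <- .add_bias(A %*% br$out$W, br$out$b)
  }
  out
}

.trunk_forward <- function(params, X) {
  H1 <- relu(.add_bias(X %*% params$trunk1$W, params$trunk1$b))
  relu(.add_bias(H1 %*% params$trunk2$W, params$trunk2$b))
}

#' Extract bottleneck embeddings
#'
#' Returns the post-ReLU activations of the second trunk layer — the shared
#' low-dimensional summary of cell state from which every protein branch
#' predicts. Entries are non-negative.
#'
#' @inheritParams forward
#' @return numeric matrix, cells x bottleneck width.
#' @export
bottleneck <- function(model, X) {
  stopifnot(inherits(model, "ctpnet_model"))
  X <- .as_input_matrix(X, model$spec)
  H <- .trunk_forward(model$params, X)
  rownames(H) <- rownames(X)
  H
}

#' Save / load a trained model
#'
#' The model file is a single serialized archive holding the architecture
#' spec, the weight arrays, the gene list used at training (so prediction can
#' auto-align new data), preprocessing metadata, a format version and a
#' weight checksum. Round-trips are bit-exact.
#'
#' @param model a `ctpnet_model`.
#' @param path file path (conventionally `.ctp`).
#' @return `save_model`: `path` invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ctpnet_model"))
  payload <- unclass(model)
  payload$checksum <- .param_checksum(model$params)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop(sprintf(
                        "cannot parse model file %s (truncated or not a model): %s",
                        path, conditionMessage(e))))
  if (is.null(payload$format_version))
    stop("file has no format version; not a model file")
  if (payload$format_version != MODEL_FORMAT_VERSION)
    stop(sprintf("model format version %s is incompatible with this build (%s)",
                 payload$format_version, MODEL_FORMAT_VERSION))
  for (field in c("spec", "params", "checksum"))
    if (is.null(payload[[field]]))
      stop(sprintf("model file is missing the '%s' field", field))
  if (!identical(.param_checksum(payload$params), payload$checksum))
    stop("model file checksum mismatch: weights corrupted")
  payload$checksum <- NULL
  class(payload$spec) <- "network_spec"
  structure(payload, class = "ctpnet_model")
}

.param_checksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  c(n = length(v), sum = sum(v), abssum = sum(abs(v)))
}

#' Evaluate an expression deterministically under a seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
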