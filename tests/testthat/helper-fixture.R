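# Shared fixtures, built lazily and cached for the whole test session.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Default desk-scale fixture: 2000 cells, 500 genes, 6 proteins, 4 types.
fx_sim <- function() fx_get("sim", function() {
  generate_paired(synthetic_config(seed = 7))
})

fx_norm <- function() fx_get("norm", function() {
  log_normalize(qc_filter(fx_sim()$expr))
})

fx_clr <- function() fx_get("clr", function() clr_transform(fx_sim()$adt))

# Full-scale training run on the fixture (the expensive shared artifact).
fx_fit <- function() fx_get("fit", function() {
  sim <- fx_sim()
  spec <- network_spec(n_features(fx_norm()), feature_names(fx_clr()))
  train(fx_norm(), fx_clr(), spec, train_config(seed = 7), labels = sim$labels)
})

# Small dataset for cheap unit tests of training and benchmarking.
small_sim <- function() fx_get("small_sim", function() {
  generate_paired(synthetic_config(n_cells = 300, n_genes = 80, n_proteins = 3,
                                   n_cell_types = 3, marker_genes_per_type = 5,
                                   seed = 1))
})

small_norm <- function() fx_get("small_norm", function() {
  log_normalize(small_sim()$expr)
})

small_clr <- function() fx_get("small_clr", function() {
  clr_transform(small_sim()$adt)
})

small_spec <- function() network_spec(n_features(small_norm()),
                                      feature_names(small_clr()),
                                      trunk_widths = c(64L, 16L),
                                      branch_width = 8L)

# A model whose weights are set by hand; all biases zero.
# layer_weights: list(trunk1=, trunk2=, branches=list(<protein>=list(hidden=, out=)))
hand_model <- function(spec, layer_weights) {
  m <- build_network(spec, seed = 1)
  m$params$trunk1$W[] <- layer_weights$trunk1
  m$params$trunk1$b[] <- 0
  m$params$trunk2$W[] <- layer_weights$trunk2
  m$params$trunk2$b[] <- 0
  for (pn in names(m$params$branches)) {
    m$params$branches[[pn]]$hidden$W[] <- layer_weights$branches[[pn]]$hidden
    m$params$branches[[pn]]$hidden$b[] <- 0
    m$params$branches[[pn]]$out$W[] <- layer_weights$branches[[pn]]$out
    m$params$branches[[pn]]$out$b[] <- 0
  }
  m
}

# 2-gene, 1-protein identity-like linear chain: output = X[, 1], X[, 2] ignored.
passthrough_model <- function() {
  spec <- network_spec(2, "P", trunk_widths = c(1L, 1L), branch_width = 1L)
  hand_model(spec, list(trunk1 = c(1, 0), trunk2 = 1,
                        branches = list(P = list(hidden = 1, out = 1))))
}
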