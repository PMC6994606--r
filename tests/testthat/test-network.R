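# closed-form trainable-parameter count for trunk widths (h1, h2), branch hb
p_count <- function(D, d, h1 = 1000, h2 = 128, hb = 64) {
  (D * h1 + h1) + (h1 * h2 + h2) + d * ((h2 * hb + hb) + (hb + 1))
}

test_that("parameter count matches the closed form", {
  m <- build_network(network_spec(100, c("A", "B")), seed = 1)
  expect_equal(n_params(m), 245770)
  expect_equal(n_params(m), p_count(100, 2))
  tiny <- build_network(network_spec(1, "A", trunk_widths = c(1L, 1L),
                                     branch_width = 1L), seed = 1)
  expect_equal(n_params(tiny), 8)
  # five random specs
  set.seed(20)
  for (i in 1:5) {
    D <- sample(10:400, 1); d <- sample(1:8, 1)
    m <- build_network(network_spec(D, paste0("p", seq_len(d))), seed = i)
    expect_equal(n_params(m), p_count(D, d))
  }
})

test_that("initialization is deterministic given the seed", {
  spec <- network_spec(30, c("A", "B"))
  m1 <- build_network(spec, seed = 42)
  m2 <- build_network(spec, seed = 42)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(spec, seed = 43)
  expect_false(identical(m1$params, m3$params))
})

test_that("invalid specs are rejected", {
  expect_error(network_spec(0, "A"), "positive")
  expect_error(network_spec(10, character(0)), "non-empty")
  expect_error(network_spec(10, c("A", "A")), "unique")
})

test_that("forward matches hand computation on a passthrough network", {
  m <- passthrough_model()
  X <- matrix(c(2, -3, 5, 1), 2, 2,   # g1 = (2, -3); g2 ignored
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  out <- forward(m, X)
  expect_equal(unname(out[, "P"]), c(2, 0))   # relu chain: 2 passes, -3 clips
  # zero weights give zero output whatever the input
  z <- hand_model(network_spec(2, "P", trunk_widths = c(1L, 1L),
                               branch_width = 1L),
                  list(trunk1 = c(0, 0), trunk2 = 0,
                       branches = list(P = list(hidden = 0, out = 0))))
  expect_equal(unname(forward(z, X)[, 1]), c(0, 0))
})

test_that("batched forward equals row-stacked single-cell forwards", {
  spec <- network_spec(15, c("A", "B"), trunk_widths = c(20L, 8L),
                       branch_width = 4L)
  m <- build_network(spec, seed = 9)
  set.seed(1)
  X <- matrix(abs(rnorm(6 * 15)), 6, 15,
              dimnames = list(paste0("c", 1:6), paste0("g", 1:15)))
  batch <- forward(m, X)
  single <- do.call(rbind, lapply(1:6, function(i)
    forward(m, X[i, , drop = FALSE])))
  expect_lt(max(abs(batch - single)), 1e-10)
})

test_that("protein outputs are isolated from other branches", {
  spec <- network_spec(10, c("A", "B", "C"), trunk_widths = c(12L, 6L),
                       branch_width = 4L)
  m <- build_network(spec, seed = 2)
  set.seed(2)
  X <- matrix(abs(rnorm(5 * 10)), 5, 10,
              dimnames = list(paste0("c", 1:5), paste0("g", 1:10)))
  before <- forward(m, X)
  m$params$branches$B$hidden$W[] <- rnorm(length(m$params$branches$B$hidden$W))
  m$params$branches$B$out$b[] <- 5
  after <- forward(m, X)
  expect_identical(before[, c("A", "C")], after[, c("A", "C")])
  expect_false(identical(before[, "B"], after[, "B"]))
})

test_that("bottleneck embeddings compose with the branch layers", {
  spec <- network_spec(12, c("A", "B"), trunk_widths = c(16L, 8L),
                       branch_width = 4L)
  m <- build_network(spec, seed = 3)
  set.seed(3)
  X <- matrix(abs(rnorm(7 * 12)), 7, 12,
              dimnames = list(paste0("c", 1:7), paste0("g", 1:12)))
  H <- bottleneck(m, X)
  expect_true(all(H >= 0))
  expect_equal(dim(H), c(7, 8))
  br <- m$params$branches$A
  manual <- pmax(H %*% br$hidden$W +
                   rep(br$hidden$b, each = 7), 0) %*% br$out$W + br$out$b
  expect_lt(max(abs(manual - forward(m, X, proteins = "A")[, 1])), 1e-12)
})

test_that("gene-dimension mismatch points the user at align_genes", {
  m <- build_network(network_spec(10, "A", trunk_widths = c(4L, 2L),
                                  branch_width = 2L), seed = 1)
  X <- matrix(1, 2, 7)
  expect_error(forward(m, X), "align_genes")
})

test_that("model save/load round-trips bit-exactly", {
  spec <- network_spec(20, c("A", "B"), trunk_widths = c(8L, 4L),
                       branch_width = 2L)
  m <- build_network(spec, seed = 5)
  m$gene_names <- paste0("g", 1:20)
  path <- withr::local_tempfile(fileext = ".ctp")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$gene_names, m$gene_names)
  expect_identical(back$spec, m$spec)
  X <- matrix(abs(rnorm(3 * 20)), 3, 20,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:20)))
  expect_identical(forward(m, X), forward(back, X))
})

test_that("corrupt or incompatible model files fail loudly", {
  spec <- network_spec(5, "A", trunk_widths = c(3L, 2L), branch_width = 2L)
  m <- build_network(spec, seed = 1)
  path <- withr::local_tempfile(fileext = ".ctp")
  save_model(m, path)
  # truncation -> parse/checksum error, not silent garbage
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:(length(raw) %/% 2)], path)
  expect_error(load_model(path), "parse|checksum|truncated")
  # version mismatch
  payload <- unclass(m)
  payload$checksum <- ctpnet:::.param_checksum(m$params)
  payload$format_version <- 999L
  saveRDS(payload, path)
  expect_error(load_model(path), "version")
  # missing required field
  payload$format_version <- m$format_version
  payload$params <- NULL
  saveRDS(payload, path)
  expect_error(load_model(path), "params")
  expect_error(load_model(tempfile()), "not found")
})

test_that("all-zero input output is determined by biases alone", {
  spec <- network_spec(4, "A", trunk_widths = c(3L, 2L), branch_width = 2L)
  m <- build_network(spec, seed = 8)
  m$params$trunk1$b[] <- c(0.5, -1, 2)
  m$params$trunk2$b[] <- c(0.1, 0.2)
  m$params$branches$A$hidden$b[] <- c(-0.3, 0.4)
  m$params$branches$A$out$b[] <- 0.7
  X <- matrix(0, 1, 4, dimnames = list("c1", paste0("g", 1:4)))
  # hand computation through the relu chain
  h1 <- pmax(m$params$trunk1$b, 0)
  h2 <- pmax(as.vector(h1 %*% m$params$trunk2$W) + m$params$trunk2$b, 0)
  a <- pmax(as.vector(h2 %*% m$params$branches$A$hidden$W) +
              m$params$branches$A$hidden$b, 0)
  expected <- as.vector(a %*% m$params$branches$A$out$W) +
    m$params$branches$A$out$b
  expect_equal(unname(forward(m, X)[1, 1]), expected, tolerance = 1e-12)
})
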