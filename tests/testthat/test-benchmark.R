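clr_like <- function(m) {
  # rows centered so the matrix passes as CLR-scale values
  sweep(m, 1, rowMeans(m))
}

test_that("correlation_report recovers perfect and inverted agreement", {
  set.seed(1)
  m <- clr_like(matrix(rnorm(40), 10, 4,
                       dimnames = list(paste0("c", 1:10), paste0("p", 1:4))))
  rep1 <- correlation_report(m, m)
  expect_equal(rep1$overall$cor, rep(1, 4))
  rep2 <- correlation_report(-m, m)
  expect_equal(rep2$overall$cor, rep(-1, 4))
  expect_equal(rep1$n_cells, 10)
})

test_that("correlation_report matches a from-scratch Pearson computation", {
  # 5-cell hand-worked pair
  imp <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(paste0("c", 1:5), "P"))
  mea <- matrix(c(2, 1, 4, 3, 6), 5, 1, dimnames = list(paste0("c", 1:5), "P"))
  textbook <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  rep <- correlation_report(imp, mea)
  expect_equal(rep$overall$cor, textbook(imp[, 1], mea[, 1]), tolerance = 1e-12)
  # random data, two-pass oracle per protein
  set.seed(8)
  A <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("c", 1:12), paste0("p", 1:5)))
  B <- matrix(rnorm(60), 12, 5, dimnames = dimnames(A))
  rep2 <- correlation_report(A, B)
  for (j in 1:5)
    expect_equal(rep2$overall$cor[j], textbook(A[, j], B[, j]),
                 tolerance = 1e-12)
})

test_that("zero-variance proteins are undefined, not zero", {
  imp <- matrix(c(1, 1, 1, 0, 1, 2), 3, 2,
                dimnames = list(paste0("c", 1:3), c("flat", "ok")))
  mea <- matrix(rnorm(6), 3, 2, dimnames = dimnames(imp))
  rep <- correlation_report(imp, mea)
  expect_true(rep$overall$undefined[rep$overall$protein == "flat"])
  expect_true(is.na(rep$overall$cor[rep$overall$protein == "flat"]))
  expect_false(rep$overall$undefined[rep$overall$protein == "ok"])
})

test_that("correlation_report intersects barcodes and reports by type", {
  set.seed(2)
  imp <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("c", 1:10), c("A", "B")))
  mea <- matrix(rnorm(16), 8, 2,
                dimnames = list(paste0("c", 3:10), c("A", "B")))
  labs <- CellLabels(paste0("c", 1:10), rep(c("T", "NK"), 5))
  rep <- correlation_report(imp, mea, labels = labs)
  expect_equal(rep$n_cells, 8)
  expect_setequal(unique(rep$by_type$cell_type), c("T", "NK"))
  expect_equal(nrow(rep$by_type), 4)
  # within-type values agree with direct computation
  t_cells <- intersect(paste0("c", seq(1, 9, 2)), rownames(mea))
  expect_equal(rep$by_type$cor[rep$by_type$cell_type == "NK" &
                                 rep$by_type$protein == "A"],
               cor(imp[setdiff(rownames(mea), t_cells), "A"],
                   mea[setdiff(rownames(mea), t_cells), "A"]))
  expect_error(correlation_report(imp[1:2, ], mea[5:8, ]), "barcodes")
})

test_that("baseline_rna_correlation sums multi-gene complexes", {
  set.seed(6)
  n <- 50
  g1 <- rpois(n, 20); g2 <- rpois(n, 20)
  counts <- cbind(chainA = g1, chainB = g2, other = rpois(n, 5))
  rownames(counts) <- paste0("c", 1:n)
  expr <- ExpressionMatrix(counts, stage = "raw")
  # protein measured exactly as the SUM of the two chains
  mea <- matrix(g1 + g2, n, 1, dimnames = list(rownames(counts), "CD3"))
  both <- baseline_rna_correlation(expr, mea,
                                   map = list(CD3 = c("chainA", "chainB")))
  expect_equal(both$cor, 1.0, tolerance = 1e-12)
  single <- baseline_rna_correlation(expr, mea, map = list(CD3 = "chainA"))
  expect_lt(single$cor, 1.0)
  # single-gene map, gene identical to protein values
  mea2 <- matrix(g1, n, 1, dimnames = list(rownames(counts), "CD3"))
  expect_equal(baseline_rna_correlation(expr, mea2,
                                        map = list(CD3 = "chainA"))$cor, 1.0)
})

test_that("missing mapped genes are reported", {
  counts <- matrix(rpois(20, 5), 10, 2,
                   dimnames = list(paste0("c", 1:10), c("g1", "g2")))
  expr <- ExpressionMatrix(counts, stage = "raw")
  mea <- matrix(rnorm(10), 10, 1, dimnames = list(rownames(counts), "P"))
  res <- baseline_rna_correlation(expr, mea, map = list(P = "absent_gene"))
  expect_true(res$undefined)
  expect_equal(res$reason, "missing gene")
  # partially missing: present genes used, missing counted
  res2 <- baseline_rna_correlation(expr, mea, map = list(P = c("g1", "nope")))
  expect_equal(res2$n_genes_used, 1L)
  expect_equal(res2$n_genes_missing, 1L)
  expect_error(baseline_rna_correlation(expr, mea, map = list(Q = "g1")),
               "not in measured")
})

test_that("out-of-cell-type evaluation predicts every cell exactly once", {
  sim <- small_sim()
  norm <- small_norm()
  clr <- small_clr()
  spec <- small_spec()
  cfg <- train_config(max_epochs = 5, seed = 1)
  res <- out_of_celltype_eval(norm, clr, sim$labels, spec, cfg)
  expect_equal(nrow(res$folds), 3)          # one model per type
  expect_equal(nrow(res$predictions), n_cells(norm))
  expect_false(anyNA(res$predictions))
  # the model that predicted each cell never saw that cell's type
  for (i in seq_len(nrow(res$folds))) {
    trained_on <- strsplit(res$folds$training_types[i], ";")[[1]]
    expect_false(res$folds$cell_type[i] %in% trained_on)
    expect_setequal(c(trained_on, res$folds$cell_type[i]),
                    unique(unclass(sim$labels)))
  }
  expect_equal(res$report$scheme, "out_of_celltype")
  # single cell type is rejected
  one <- CellLabels(cell_barcodes(norm), rep("only", n_cells(norm)))
  expect_error(out_of_celltype_eval(norm, clr, one, spec, cfg),
               "at least 2")
})

test_that("cross-dataset evaluation on the training set matches in-sample", {
  sim <- small_sim()
  norm <- small_norm()
  clr <- small_clr()
  fit <- train(norm, clr, small_spec(), train_config(max_epochs = 10, seed = 2),
               labels = sim$labels)
  res <- cross_dataset_eval(fit$model, sim$expr, sim$adt, qc = FALSE)
  insample <- correlation_report(forward(fit$model, norm), clr)
  expect_equal(res$report$overall$cor, insample$overall$cor, tolerance = 1e-12)
  expect_equal(res$alignment$n_zero_filled, 0)
})

test_that("cross-dataset evaluation zero-fills unseen genes and flags them", {
  sim <- small_sim()
  fit <- train(small_norm(), small_clr(), small_spec(),
               train_config(max_epochs = 5, seed = 2), labels = sim$labels)
  # test data missing 10 of the model's genes
  sub <- sim$expr[, 1:(n_features(sim$expr) - 10)]
  expect_warning(
    res <- cross_dataset_eval(fit$model, sub, sim$adt, qc = FALSE),
    regexp = NA)
  expect_equal(res$alignment$n_zero_filled, 10)
  expect_true(all(is.finite(res$report$overall$cor)))
})

test_that("disjoint protein panels give an explicit empty report", {
  sim <- small_sim()
  fit <- train(small_norm(), small_clr(), small_spec(),
               train_config(max_epochs = 3, seed = 2), labels = sim$labels)
  other <- sim$adt
  colnames(other$values) <- paste0("other_", colnames(other$values))
  res <- cross_dataset_eval(fit$model, sim$expr, other, qc = FALSE)
  expect_equal(res$report$status, "no shared proteins")
  expect_null(res$report$overall)
})
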