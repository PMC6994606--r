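#' Configuration for the paired RNA/ADT simulator
#'
#' Defines a synthetic CITE-seq-like experiment with known ground truth. The
#' defaults describe a desk-scale immune-population-like dataset: 2000 cells
#' in 4 cell types, 500 genes of which each type has 10 upregulated markers,
#' and 6 surface proteins whose true abundance mixes a cognate-gene signal
#' with a multi-gene latent state (see [generate_paired]).
#'
#' @param n_cells,n_genes,n_proteins,n_cell_types dataset dimensions.
#' @param marker_genes_per_type genes upregulated specifically in each type.
#' @param rna_dispersion,adt_dispersion negative-binomial dispersion `phi`
#'   (variance `mu + phi * mu^2`); 0 means Poisson.
#' @param protein_rna_coupling fraction in \[0, 1\] of each protein's signal
#'   driven by its cognate gene's expression deviation, the remainder by a
#'   multi-gene latent state; CITE-seq proteins correlate only weakly with
#'   their own transcript, hence the low default 0.4.
#' @param library_size_range per-cell total UMI count range (uniform).
#' @param include_unseen_type add one extra cell type (labelled
#'   `"unseen_type"`) intended to be excluded from training, emulating a
#'   cross-tissue scenario with a novel population.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_cells = 2000L, n_genes = 500L, n_proteins = 6L,
                             n_cell_types = 4L, marker_genes_per_type = 10L,
                             rna_dispersion = 0.1, adt_dispersion = 0.1,
                             protein_rna_coupling = 0.4,
                             library_size_range = c(4000, 5000),
                             include_unseen_type = FALSE, seed = 0L) {
  stopifnot(n_cells >= 2, n_genes >= 2, n_proteins >= 1, n_cell_types >= 1,
            marker_genes_per_type >= 0, rna_dispersion >= 0,
            adt_dispersion >= 0, protein_rna_coupling >= 0,
            protein_rna_coupling <= 1, length(library_size_range) == 2,
            all(library_size_range > 0),
            library_size_range[1] <= library_size_range[2])
  total_types <- n_cell_types + as.integer(include_unseen_type)
  if (marker_genes_per_type * total_types + n_proteins > n_genes)
    stop("not enough genes for the requested marker sets and cognate genes")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_proteins = as.integer(n_proteins),
                 n_cell_types = as.integer(n_cell_types),
                 marker_genes_per_type = as.integer(marker_genes_per_type),
                 rna_dispersion = rna_dispersion,
                 adt_dispersion = adt_dispersion,
                 protein_rna_coupling = protein_rna_coupling,
                 library_size_range = library_size_range,
                 include_unseen_type = isTRUE(include_unseen_type),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Generate a paired RNA/ADT dataset with known ground truth
#'
#' Simulates the data regime of a CITE-seq experiment:
#'
#' * Cells are assigned to cell types; each type upregulates its own marker
#'   genes (log-fold +1.5). Gene base abundances are log-normal; every gene
#'   also carries per-cell log-normal biological variation, stronger for the
#'   genes wired into protein signals.
#' * RNA counts are negative binomial around the cell's library size times
#'   its relative expression.
#' * Each protein's true log-abundance is
#'   `coupling * eta_cognate + (1 - coupling) * u`, where `eta_cognate` is
#'   its cognate gene's per-cell log-deviation (a within-type signal, so at
#'   `coupling = 1` the protein tracks that transcript) and `u` is a
#'   standardized multi-gene latent. The latent itself mixes two kinds of
#'   cell-type structure: the cell's position along a few continuous
#'   expression *programs* (each type sits somewhere in program space, its
#'   cells drift around that position, and dedicated expressed "sensor"
#'   genes read each program out — so related types interpolate one another
#'   and the mapping transfers to types absent from training), and a
#'   type-coherent loading on each type's marker block (structure tied to
#'   type identity itself, which does not transfer). As in real data, cell
#'   type is the dominant latent variable behind surface-protein
#'   heterogeneity, but it acts through the transcriptome.
#' * ADT counts are negative binomial around `100 * exp(true level)`.
#'
#' @param config a [synthetic_config].
#' @return A list of class `ctpnet_sim`: `expr` ([ExpressionMatrix] raw),
#'   `adt` ([ProteinMatrix] counts), `labels` ([CellLabels]), and `truth`
#'   (list: `true_level` cells x proteins log-scale, `true_abundance` its
#'   exp, `true_clr` the CLR of true abundances, `multi_latent`,
#'   `cognate_latent`, `cognate_genes`, `loading` proteins x genes implied
#'   weight matrix, `marker_genes` per type, `program_genes` per program,
#'   `program_beta` sensor coefficients, `type_programs` type positions,
#'   `program_activity` per-cell program values, `gamma` protein-program
#'   loadings, `type_offsets` realized per-type latent means, `cell_types`,
#'   `library_sizes`).
#' @export
generate_paired <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    total_types <- cfg$n_cell_types + as.integer(cfg$include_unseen_type)
    type_names <- c(paste0("type", seq_len(cfg$n_cell_types)),
                    if (cfg$include_unseen_type) "unseen_type")
    # unseen type, when present, is a small added population (10% of cells)
    probs <- if (cfg$include_unseen_type)
      c(rep(0.9 / cfg$n_cell_types, cfg$n_cell_types), 0.1)
    else rep(1 / cfg$n_cell_types, cfg$n_cell_types)
    cell_type <- sample(type_names, cfg$n_cells, replace = TRUE, prob = probs)
    barcodes <- sprintf("cell%04d", seq_len(cfg$n_cells))
    genes <- sprintf("gene%03d", seq_len(cfg$n_genes))

    # gene roles: per-type markers, per-protein cognate genes, loading pool
    shuffled <- sample(genes)
    marker_genes <- list()
    k <- 0
    for (ty in type_names) {
      marker_genes[[ty]] <- shuffled[k + seq_len(cfg$marker_genes_per_type)]
      k <- k + cfg$marker_genes_per_type
    }
    cognate_genes <- shuffled[k + seq_len(cfg$n_proteins)]
    k <- k + cfg$n_proteins
    loading_pool <- shuffled[(k + 1):cfg$n_genes]
    proteins <- paste0("protein", seq_len(cfg$n_proteins))
    names(cognate_genes) <- proteins

    # base abundance; cognate genes boosted so their counts are informative
    base_mu <- stats::setNames(stats::rlnorm(cfg$n_genes, 0, 1), genes)
    base_mu[cognate_genes] <- 20 * exp(stats::rnorm(cfg$n_proteins, 0, 0.2))

    # Cell state beyond type identity: K continuous expression programs.
    # Each type occupies a position in program space and its cells drift
    # around it, so related types interpolate one another — a model trained
    # without one type can still place that type's cells on the shared
    # program axes it learned from the others.
    K <- 3L
    n_prog <- min(15L, length(loading_pool) %/% (K + 1L))
    program_genes <- list()
    for (k in seq_len(K)) {
      program_genes[[k]] <- loading_pool[(k - 1) * n_prog + seq_len(n_prog)]
    }
    all_programs <- unlist(program_genes)
    z_type <- matrix(stats::rnorm(total_types * K), total_types, K,
                     dimnames = list(type_names, NULL))
    zc <- z_type[cell_type, , drop = FALSE] +
      0.5 * matrix(stats::rnorm(cfg$n_cells * K), cfg$n_cells, K)
    rownames(zc) <- barcodes

    # program, marker and cognate genes are moderately-to-highly expressed,
    # so their counts carry usable information about the latent state
    # (uniform base levels keep the elevated marker mass symmetric across
    # types, so library-size renormalization does not encode type identity)
    all_markers <- unlist(marker_genes, use.names = FALSE)
    base_mu[all_programs] <- 8
    base_mu[all_markers] <- 8

    # per-gene biological log-sd: program genes are read through their own
    # noise; markers vary some within type; background genes vary little
    sigma <- stats::setNames(rep(0.2, cfg$n_genes), genes)
    sigma[all_programs] <- 0.3
    sigma[all_markers] <- 0.5
    sigma[cognate_genes] <- 0.6

    marker_lfc <- 1.5
    eta <- matrix(stats::rnorm(cfg$n_cells * cfg$n_genes), cfg$n_cells,
                  cfg$n_genes, dimnames = list(barcodes, genes))
    eta <- sweep(eta, 2, sigma, `*`)
    log_lambda <- sweep(eta, 2, log(base_mu), `+`)
    for (ty in type_names) {
      sel <- cell_type == ty
      log_lambda[sel, marker_genes[[ty]]] <-
        log_lambda[sel, marker_genes[[ty]]] + marker_lfc
    }
    # program genes are sensors of their program's activity; half are
    # induced and half repressed, so program swings are mass-neutral and do
    # not leak into every gene through library-size renormalization
    beta <- stats::setNames(stats::runif(length(all_programs), 0.4, 1) *
                              sample(c(-1, 1), length(all_programs),
                                     replace = TRUE),
                            all_programs)
    for (k in seq_len(K)) {
      pg <- program_genes[[k]]
      log_lambda[, pg] <- log_lambda[, pg] + outer(zc[, k], beta[pg])
    }
    lambda <- exp(log_lambda)
    rho <- lambda / rowSums(lambda)

    lib <- stats::runif(cfg$n_cells, cfg$library_size_range[1],
                        cfg$library_size_range[2])
    counts <- matrix(.rnb(length(rho), rho * lib, cfg$rna_dispersion),
                     cfg$n_cells, cfg$n_genes, dimnames = dimnames(rho))

    # Protein signals. The multi-gene latent mixes (a) the cell's program
    # activities — type structure that interpolates to unseen types because
    # the program-gene sensors are shared — and (b) a type-coherent loading
    # on every type's marker block, protein structure that is tied to type
    # identity itself and does not transfer out of type.
    log_dev <- sweep(log_lambda, 2, log(base_mu), `-`)
    loading <- matrix(0, cfg$n_proteins, cfg$n_genes,
                      dimnames = list(proteins, genes))
    gamma <- matrix(stats::rnorm(cfg$n_proteins * K), cfg$n_proteins, K,
                    dimnames = list(proteins, NULL))
    cognate_latent <- multi_latent <- matrix(
      0, cfg$n_cells, cfg$n_proteins, dimnames = list(barcodes, proteins))
    marker_coef <- 0.5
    w_program <- sqrt(0.7)
    for (p in proteins) {
      w <- stats::setNames(numeric(cfg$n_genes), genes)
      for (ty in type_names) {
        a_ty <- stats::rnorm(1)
        w[marker_genes[[ty]]] <- marker_coef * a_ty /
          max(1, cfg$marker_genes_per_type)
      }
      mark_raw <- as.vector(log_dev %*% w)
      prog_raw <- as.vector(zc %*% gamma[p, ])
      std <- function(x) (x - mean(x)) / stats::sd(x)
      u <- w_program * std(prog_raw) + sqrt(1 - w_program^2) * std(mark_raw)
      multi_latent[, p] <- 0.6 * u
      cognate_latent[, p] <- eta[, cognate_genes[p]]
      # record the implied gene weights (program genes via their sensors)
      loading[p, ] <- w
      for (k in seq_len(K)) {
        pg <- program_genes[[k]]
        loading[p, pg] <- loading[p, pg] + gamma[p, k] * beta[pg]
      }
    }
    # realized per-(type, protein) mean latent levels, recorded as truth
    offsets <- matrix(0, total_types, cfg$n_proteins,
                      dimnames = list(type_names, proteins))
    for (p in proteins)
      offsets[, p] <- tapply(multi_latent[, p],
                             factor(cell_type, levels = type_names), mean)
    true_level <- cfg$protein_rna_coupling * cognate_latent +
      (1 - cfg$protein_rna_coupling) * multi_latent
    true_abundance <- exp(true_level)
    adt_mu <- 100 * true_abundance
    adt <- matrix(.rnb(length(adt_mu), adt_mu, cfg$adt_dispersion),
                  cfg$n_cells, cfg$n_proteins, dimnames = dimnames(adt_mu))

    lg <- log(true_abundance)
    true_clr <- lg - rowMeans(lg)

    list(expr = ExpressionMatrix(counts, stage = "raw"),
         adt = ProteinMatrix(adt, stage = "counts"),
         labels = CellLabels(barcodes, cell_type),
         truth = list(true_level = true_level,
                      true_abundance = true_abundance,
                      true_clr = true_clr,
                      multi_latent = multi_latent,
                      cognate_latent = cognate_latent,
                      cognate_genes = cognate_genes,
                      loading = loading,
                      marker_genes = marker_genes,
                      program_genes = program_genes,
                      program_beta = beta,
                      type_programs = z_type,
                      program_activity = zc,
                      gamma = gamma,
                      type_offsets = offsets,
                      cell_types = stats::setNames(cell_type, barcodes),
                      library_sizes = stats::setNames(lib, barcodes)),
         config = cfg) -> out
    class(out) <- "ctpnet_sim"
    out
  })
}

#' @export
print.ctpnet_sim <- function(x, ...) {
  cat(sprintf("ctpnet_sim: %d cells, %d genes, %d proteins, %d cell types (seed %d)\n",
              n_cells(x$expr), n_features(x$expr), n_features(x$adt),
              length(unique(unclass(x$labels))), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk as standard files
#'
#' Writes the RNA counts as a 10x-style MTX triplet (matrix.mtx genes x
#' cells, features.tsv, barcodes.tsv), the ADT counts as a proteins x cells
#' CSV, the labels as a two-column CSV, and the ground truth as an RDS
#' archive. [read_counts] round-trips the counts exactly.
#'
#' @param sim a `ctpnet_sim` from [generate_paired].
#' @param dir output directory (created if missing).
#' @return character vector of the six file paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "ctpnet_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create directory %s", dir))
  counts <- sim$expr$values
  sp <- Matrix::Matrix(t(counts), sparse = TRUE)      # genes x cells
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "adt.csv", "labels.csv", "truth.rds"))
  Matrix::writeMM(sp, paths[1])
  utils::write.table(data.frame(id = colnames(counts), name = colnames(counts)),
                     paths[2], sep = "\t", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  writeLines(rownames(counts), paths[3])
  adt <- t(sim$adt$values)                            # proteins x cells
  utils::write.table(
    data.frame(protein = rownames(adt), adt, check.names = FALSE),
    paths[4], sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(barcode = names(sim$labels),
                              cell_type = unclass(sim$labels)),
                   paths[5], row.names = FALSE, quote = FALSE)
  saveRDS(sim$truth, paths[6])
  invisible(paths)
}
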