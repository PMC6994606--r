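Package: ctpnet
Title: Imputation of Cell-Surface Protein Abundance from Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes the relative abundance of cell-surface proteins for
    single-cell RNA-seq data by learning a transcriptome-to-protein mapping
    from paired CITE-seq/REAP-seq training data. Provides the standard
    preprocessing transforms (library-size log-normalization of RNA counts,
    centered log-ratio transformation of antibody-derived-tag counts), a
    multiple-branch deep neural network regression model fitted by minibatch
    Adam under an L1 objective, holdout and leave-one-cell-type-out
    benchmarking with per-protein and within-cell-type correlation reports,
    a permutation-based gene influence score for network interpretation, and
    a negative-binomial simulator of paired RNA/protein data with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
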