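Package: morphodose
Title: Dose-Response Analysis of Cell Painting Morphological Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for concentration-response analysis
    of high-content Cell Painting experiments and companion omics readouts.
    Covers quality control of per-cell feature tables, robust normalization
    against unexposed controls (median/MAD), empirical-Bayes location-scale
    batch correction across microplates, aggregation to image-, well- and
    treatment-level profiles, a per-feature ANCOVA concentration screen with
    Bonferroni family-wise control, UMAP embedding, sparse PLS-DA
    classification with leave-one-plate-out cross-validation, differential
    abundance statistics for lipidomics/metabolomics tables (ANOVA + Tukey
    HSD, volcano classification, clustered heatmaps), released-metal mass
    fraction arithmetic, and a synthetic plate-structured data generator with
    known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mixOmics,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
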