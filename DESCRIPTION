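Package: lipidcc
Title: Case-Control Analysis of Untargeted Plasma Lipidomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for case-control analysis of
    untargeted LC-MS lipidomics feature tables: total-mean-area normalisation,
    stratified detection filtering, log2 transformation, empirical-Bayes
    (ComBat-model) batch correction, PCA-based outlier and pooled-QC assessment,
    per-phenotype feature-space KNN imputation, covariate-adjusted per-metabolite
    logistic association with Benjamini-Hochberg control, and a leakage-safe
    two-stage classifier built from bootstrapped random-forest variable-importance
    rank aggregation followed by recursive feature elimination with a
    size-tolerance rule, evaluated on a held-out test set. Includes a seeded
    synthetic-cohort generator with known ground truth (batch effects,
    left-censored missingness, monotone group effects, realistic covariates) so
    every stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
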