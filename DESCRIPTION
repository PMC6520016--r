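Package: careindex
Title: Event-Based Staging and Conversion Prediction for Mild Cognitive
    Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements an event-based probabilistic staging pipeline for
    predicting progression from mild cognitive impairment (MCI) to
    Alzheimer's disease. Per-biomarker event/non-event densities are fitted
    with constrained two-component Gaussian mixtures, the maximum-likelihood
    ordering of biomarker abnormality events is estimated by multi-start
    greedy search (with optional Metropolis sampling of positional
    uncertainty), and each subject is assigned a disease stage (the CARE
    index) by maximum-likelihood staging under that ordering. Includes ROC
    analysis with Youden-optimal thresholds, cross-cohort threshold
    transfer, diagnostic odds/risk ratios with Woolf and Katz confidence
    intervals, DeLong comparison of correlated AUCs, group-comparison
    statistics, FDR-corrected change-score regressions, and a synthetic
    two-cohort generator emulating the discovery/validation design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
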