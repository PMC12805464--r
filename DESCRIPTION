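Package: ptauscreen
Title: Screening Performance Evaluation for a Plasma pTau217 Amyloid Pre-Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Evaluates a continuous plasma biomarker (tau phosphorylated at
    threonine 217, pTau217) as a rule-out pre-screen for amyloid pathology
    against a binary amyloid PET reference. Provides ROC/AUC estimation with
    DeLong confidence intervals and forest tables, predictiveness-curve
    ("integrated risk") profiling with nonparametric and monotone (isotonic)
    estimators and prevalence re-weighting, prevalence-adjusted screening
    metrics (PPV, NPV, screen-out rate, additional screening required,
    PET scans saved), rule-out cutoff selection, clinical-trial enrollment
    planning, Centiloid-threshold classification, and a calibrated synthetic
    cohort generator with lower-limit-of-quantification censoring.
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
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
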