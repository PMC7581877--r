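Package: fhmethyl
Title: Tiered Differential Methylation and Machine-Learning Discrimination
    for Familial Hypercholesterolemia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for blood DNA methylation array studies of
    clinical familial hypercholesterolemia (FH) comparing mutation-negative
    with mutation-positive patients. Provides a synthetic methylation-cohort
    generator (two-group design, leukocyte cell mixtures, spiked group
    effects, SNP-artifact probes), probe quality-control filtering,
    reference-based leukocyte deconvolution by constrained projection,
    per-CpG covariate-adjusted linear models with empirical-Bayes variance
    moderation, empirical-null inflation correction of test statistics,
    Benjamini-Hochberg false discovery rates, candidate-gene tier analysis
    with flanking-window probe selection, a stability-selected
    gradient-boosting classifier with repeated-split AUC and label
    permutation significance, and correlation-based in-silico validation
    against expression or phenotype tables. Results are returned as tibbles
    with broom-style tidy() and glance() methods and ggplot2 autoplot()
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    xgboost
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
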