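Package: jembuild
Title: Build and Validate Job-Exposure Matrices from Cohort Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs job-exposure matrices (JEMs) from individual-level
    cohort records carrying hierarchical occupation (PCS-2003 style) and
    activity-sector (NAF-2008 style) codes, using the group-based frequency
    method: per-group exposure prevalences estimated on a learning split,
    dichotomized at an F1-optimal threshold chosen on a held-out test split,
    and validated with Cohen's kappa, ROC-AUC, sensitivity, specificity and
    F1. Includes mixed-scale exposure dichotomization (binary, Likert, Borg
    RPE, effort-reward imbalance), a tree/random-forest/gradient-boosting
    comparator harness with inverse-probability class weighting and
    cross-validated tuning, and a synthetic-cohort generator with known
    ground truth for internal validation.
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
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
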