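Package: expandnet
Title: Multifactorial Prediction of Post-Therapy T-Cell Clonal Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for modelling post-immunotherapy T-cell
    clonal expansion from pre-treatment clinical, tumor and circulating
    patient attributes on small cohorts. Encodes nineteen attributes into a
    36-column design (raw and log1p transforms), fits an elastic-net
    regression with leave-one-out hyperparameter selection nested inside an
    outer leave-one-out evaluation, and reports held-out variance explained.
    Includes permutation tests of association based on cross-validated
    error (global response permutation and per-category conditional
    permutation), category ablations, a durable-clinical-benefit triage
    comparison against single biomarkers, and a synthetic-cohort generator
    with ground truth for calibration and recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang,
    randomForest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    yaml
Config/testthat/edition: 3
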