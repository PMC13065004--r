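Package: permfitr
Title: Permutation Feature Importance Testing for Machine Learning Risk
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Permutation-based feature importance testing (PermFIT) with
    formal statistical inference for black-box classifiers, applied to
    postoperative-infection risk prediction in ICU surgical cohorts.
    Provides a seeded synthetic electronic-health-record cohort generator
    with a known outcome model, four learners behind a uniform
    probability-prediction contract (RBF support vector machine, random
    forest, gradient boosting, and a bootstrap-filtered stable deep
    neural network ensemble implemented with 'RcppArmadillo'), per-feature
    importance z-tests with cross-fitting, a select-then-refit stratified
    10-fold cross-validation pipeline, and imbalance-aware evaluation
    metrics (ROC-AUC, precision-recall AUC) with confidence intervals and
    report export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
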