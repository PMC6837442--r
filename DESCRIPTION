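Package: valbias
Title: Monte-Carlo Study of Machine-Learning Validation Bias with Small Samples
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying optimistic bias in machine-learning
    performance estimates obtained with small samples. Generates pure-noise
    and discriminable Gaussian datasets, implements two-sample t-test and
    SVM-RFE feature selection, grid-tuned RBF-SVM and penalized logistic
    classifiers, and five validation protocols (train/test split, K-fold CV,
    nested CV, and two partially nested variants) with an auditable leakage
    ledger recording which samples each development stage touched. Includes
    experiment sweeps over sample size, feature count, tuning-grid size, fold
    count and feature-to-sample ratio, two small illustrative overfitting
    demonstrations, and literature-survey statistics relating reported
    accuracy to sample size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
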