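Package: dynstates
Title: Time-Varying Functional Network Connectivity States and Task Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates time-varying functional network connectivity (FNC)
    from fMRI component time-series using tapered sliding windows with
    graphical-lasso regularization, extracts reoccurring whole-brain FNC
    states by two-stage k-means clustering with exemplar initialization,
    characterizes states with signed-network modularity and participation
    coefficients against degree-preserving nulls, relates state occurrence
    and dwell time to hemodynamically convolved task events via permutation
    inference, identifies task-specific regional connections, and compares
    time-varying against static connectivity in explaining behaviour,
    including a multiple-holdout sparse partial least squares association.
    A synthetic cohort generator with planted covariance states provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
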