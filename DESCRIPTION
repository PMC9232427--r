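Package: mouec
Title: Whole-Brain Effective Connectivity from the Multivariate
    Ornstein-Uhlenbeck Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates directed whole-brain effective connectivity from
    BOLD-like regional time series by fitting a multivariate
    Ornstein-Uhlenbeck process to the zero-lag and lagged spatial
    covariances, with the admissible connections constrained by a
    density-thresholded structural connectome. Includes narrowband
    filtering and covariance estimation, connectome-feature
    classification of groups and conditions with repeated splits and
    surrogate baselines, recursive-feature-elimination extraction of
    discriminative support networks, a permutation-based network
    statistic on structural matrices with family-wise error control,
    and a synthetic-cohort generator so the full pipeline runs
    end-to-end without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
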