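Package: dynconn
Title: Static and Dynamic Functional Network Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for static and dynamic functional network connectivity
    (FNC) analysis of multi-subject component time courses: quality control
    and conditioning of time courses (detrending, MAD-based despiking,
    zero-phase Butterworth low-pass filtering, multitaper spectra), static
    FNC matrices with covariate-adjusted multivariate group analysis,
    tapered sliding-window connectivity regularized with the graphical
    LASSO, k-means cluster-state analysis with dwell-time and transition
    metrics, meta-state dynamism metrics in city-block geometry, and the
    accompanying group statistics (automatic test selection, Box-Cox
    gating, partial correlations with nuisance covariates, Dubey and
    Armitage-Parmar effective-number-of-tests Bonferroni correction).
    Includes a synthetic cohort generator with hidden-Markov switching
    covariance states for validating every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ica,
    jsonlite,
    MASS,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
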