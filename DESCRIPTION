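Package: kubofit
Title: Least-Squares Fitting of Two-Dimensional Infrared Spectra to
    Generalized Kubo Line-Shape Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward modeling and nonlinear least-squares fitting of
    two-dimensional infrared (2D IR) waiting-time series in the measurement
    domain (pump coherence delay, waiting time, probe frequency).  Implements
    the third-order response of a three-level vibrational system under a
    generalized Kubo frequency-fluctuation correlation function, a
    Gauss-Newton fitting engine governed by a scale-invariant gradient norm
    (SIGN) stopping criterion with stall detection and random restarts,
    parameter covariance, confidence-interval and variance-inflation-factor
    diagnostics, the centerline-slope (CLS) reference method with corrected
    propagation of Kubo-time uncertainty into the linear-absorption step, and
    a synthetic-data generator so that every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
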