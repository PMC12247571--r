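Package: beamconn
Title: Robust Source-Level Phase-Coupling Detection with Dual-Dipole
    Beamformers and Sensor-Array Subsampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frequency-domain simulation and source reconstruction toolkit for
    robust all-to-all phase-coupling detection in MEG. Provides an analytic
    spherical-conductor forward model, a parametrized generator of complex
    sensor-level Fourier coefficients with controlled source coherence, single-
    and two-dipole unit-gain (LCMV/DICS-type) beamformers with vectorized
    all-pairs cross-spectral estimation, a null-coherence bias estimate based on
    spatial-filter inner products, sensor-array subsampling with z-like
    aggregation, and 6-dimensional connection detection with free-response ROC
    evaluation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
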