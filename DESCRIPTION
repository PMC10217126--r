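Package: mwtomo
Title: Microwave Tomography Simulation and Convolutional Tumor Detection
    for Breast Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation and detection pipeline for 2D microwave
    breast tomography. Generates stochastic dielectric breast phantoms with
    four density classes and optional malignant inclusions, solves the
    transverse-magnetic electromagnetic scattering problem with a Method of
    Moments forward solver (direct and FFT-accelerated conjugate-gradient
    variants, validated against an analytic cylindrical-harmonics solution),
    corrupts multistatic scattering matrices with additive white Gaussian
    noise at prescribed signal-to-noise ratios, trains a 10-layer
    convolutional neural network that scores each scattering matrix for the
    presence of tumor tissue, and evaluates detection performance with ROC
    curves, area under the ROC, equal error rate, and threshold metrics,
    including tumor-size-stratified evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
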