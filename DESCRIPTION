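Package: gaitid
Title: Segmentation-Free Gait-Based User Identification from Smart-Insole
    Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies users from partial walking data recorded by bilateral
    smart-insole accelerometers, without step detection or gait segmentation.
    A two-layer stacked LSTM is trained on contiguous windows of random size
    (20 to 200 samples at 30 Hz) and random location so that a single model
    scores windows of any length at test time. Includes a harmonic-model
    simulator of multi-user insole accelerometer datasets, per-channel
    z-score normalization, random-window samplers, stratified five-fold
    cross-validation, and accuracy reports by window size and by data rate.
    The recurrent network and its backpropagation-through-time gradients are
    implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
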