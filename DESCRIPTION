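Package: cpclock
Title: Oscillator-Bank Recurrent-Network Internal Clock Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an internal-clock model of human interval timing built
    on a bank of twelve gamma-band oscillators read out by an Elman simple
    recurrent network. Four dials of the network map onto cognitive
    constructs: attention (length of the training window), memory (hidden
    layer size), iterative learning (epochs) and clock plasticity (Fahlman
    offset on the sigmoid derivative). The package trains the clock, free-runs
    it to obtain millisecond-wise prediction error, summarises each run by a
    temporal dispersion coefficient (slope of cumulative mean Euclidean error
    over time), sweeps the full parameter factorial with repeated-measures
    ANOVA summaries, fits a feed-forward meta-model from parameters to
    dispersion, and couples a trainable prior network to the frozen meta-model
    so that neuropsychological scores and age predict individual temporal
    reproduction errors. A seeded synthetic-cohort generator emulates the
    reference study's participant structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
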