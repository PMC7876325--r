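Package: metabosc
Title: Weighted Networks of Non-Autonomous Kuramoto Oscillators for Cell
    Energy Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates cellular energy metabolism as two distance-weighted,
    all-to-all ring networks of non-autonomous Kuramoto phase oscillators
    (glycolysis and oxidative phosphorylation), each driven by non-autonomous
    glucose and oxygen supply oscillators and coupled to the mean field of the
    other network. Provides fixed-step Runge-Kutta and adaptive embedded
    Runge-Kutta integration of the governing phase equations, piecewise
    quadratic coupling schedules, finite-time synchronization analysis (phase
    coherence, bounded phase-difference detection, Kuramoto order-parameter
    statistics and a two-network modified order parameter), a six-mode regime
    classifier, parameter-plane sweeps over the inter-network coupling
    strengths, a time-varying scenario emulating glycolytic oscillations of
    starved HeLa cells, and labelled synthetic fixtures for validating every
    metric and classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
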