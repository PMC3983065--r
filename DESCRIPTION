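Package: spikethresh
Title: Adaptive Spike-Threshold Models for Intracellular Voltage Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling spike-threshold adaptation from intracellular
    membrane-potential recordings. Measures empirical spike thresholds with a
    dV/dt onset criterion, fits a first-order adaptive-threshold model (a
    smooth two-slope steady-state curve tracked with a short time constant) by
    maximizing the gamma spike-coincidence factor with CMA-ES, validates
    parameter recovery on exponential integrate-and-fire simulations with
    known ground-truth thresholds, and quantifies the functional consequences
    of fast threshold adaptation through the effective signal (voltage minus
    dynamic threshold), its variance reduction and its shortened
    autocorrelation half-height width.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
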