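Package: cptstates
Title: Engagement-State Analysis of Calcium Imaging During the Rodent
    Continuous Performance Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-cell calcium-imaging population
    recordings acquired while rodents perform a touchscreen continuous
    performance test. Provides signal-detection-theory behavioral scoring
    (d-prime, criterion c, latency series, disengagement periods),
    peri-event neuron modulation classification against a circular
    permutation null, two-state Gaussian hidden Markov model inference of
    engaged and disengaged population states with event-conditioned state
    posteriors and forward cross-validation, and state-conditioned pairwise
    correlation network characterization (sign-flip pair significance,
    exponential spatial decay fits, K-means cluster metrics). Includes a
    synthetic session generator with known ground truth so every stage is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
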