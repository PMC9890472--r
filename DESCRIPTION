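Package: popout
Title: Simulation and Decoding Pipeline for Degraded-Speech EEG and Pupillometry Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end tools for studying how prior written information
    changes neurophysiological responses to degraded speech ("pop-out").
    Provides a synthetic-data generator that emulates a two-presentation
    clarity-rating experiment with sine-wave and noise-vocoded sentence
    stimuli, a gammatone-filterbank auditory model for 2-8 Hz envelope
    extraction, deterministic EEG preprocessing, a backward (stimulus
    reconstruction) temporal-response-function decoder with ridge
    regularization, Hanning-taper time-frequency and induced-power
    analysis, nonparametric cluster-based permutation statistics, and
    pupillometry preprocessing. All stages are driven by injectable,
    known condition effects so that every analysis has a recoverable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
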