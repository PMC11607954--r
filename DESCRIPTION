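Package: radarhr
Title: Contactless Radar-Based Heart Rate Estimation and Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating heart rate from continuous-wave
    radar recordings of chest-surface micro-motion: I/Q phase demodulation to
    displacement, extraction of the 16-80 Hz heart-sound band, signal-quality
    driven multi-channel selection, S1/S2 heart-sound segmentation with a
    duration-constrained hidden semi-Markov model, interbeat-interval and
    heart-rate aggregation with exclusion and outlier rules, and the full
    method-comparison toolbox (modified Bland-Altman analysis, Schuirmann two
    one-sided equivalence tests, Hedges g(z), a priori sample-size planning).
    Includes a seeded synthetic radar-bed data generator with known ground
    truth so every stage is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
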