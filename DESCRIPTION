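Package: p300tour
Title: Simulation, Decoding and Evaluation of a P300 Oddball
    Destination-Selection Brain-Computer Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline toolkit for a six-stimulus P300 oddball brain-computer
    interface that selects travel destinations in two steps (continent, then
    place). Simulates ground-truthed oddball EEG sessions with an injectable
    event-related-potential template, implements the full signal-processing
    chain (downsampling, common average reference, 0.5-10 Hz band-pass,
    200-600 ms epoching, baseline correction, feature flattening), trains a
    stepwise linear discriminant analysis (SWLDA) classifier with hard 0/1
    epoch labels, aggregates labels into blink-vote selections, and evaluates
    performance: selection accuracy, Wolpaw information transfer rate,
    blink-subsampling curves, per-channel feature counts, Likert questionnaire
    summaries, and per-timepoint permutation t-tests with Benjamini-Yekutieli
    false-discovery-rate masking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
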