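Package: msrqa
Title: Microstate and Recurrence Quantification Analysis for EEG
    Auditory Attention Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decodes which of two competing speakers a listener attends
    from multichannel EEG. Segments EEG into quasi-stable microstates
    (global field power peaks, polarity-invariant clustering, global
    explained variance, backfitting) and summarises their dynamics
    (mean GFP, occurrence, duration, coverage); quantifies nonlinear
    dynamics of derived scalar series with recurrence plots and eight
    recurrence quantification measures (RR, DET, L_MEAN, L_MAX, ENTR,
    TT, V_max, RPDE); screens features with Kolmogorov-Smirnov and
    Mann-Whitney tests; and classifies attention with KNN, SVM, LSTM,
    Bi-LSTM and a GRU-CNN deep Q-learning agent. Includes a synthetic
    EEG generator with planted microstate dynamics so the whole
    pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
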