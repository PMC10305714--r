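Package: driveact
Title: Classification of Primary and Secondary Driver Activities from
    EOG and Accelerometer Signals
Version: 0.1.0
Authors@R:
    person("driveact", "developers", email = "driveact@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for recognising sixteen primary and
    secondary car-driver activities from smart-glasses recordings of
    electrooculography (EOG) and tri-axial acceleration.  Provides a
    synthetic-recording generator emulating the JINS MEME ES_R CSV
    dialect, a signal-conditioning chain (zero-phase Butterworth
    low-pass, differencing detrend, median plus Hamming-window FIR
    smoothing, 50 Hz synchronisation, z-score normalisation, sliding
    windows and fixed-length resampling), a one-dimensional
    convolutional neural network trained with Adam on categorical
    cross-entropy, and evaluation reports with per-class, type-level
    and binary primary/secondary metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
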