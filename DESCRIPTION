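Package: rbdscreen
Title: Minimal-Sensor Screening for REM Sleep Behaviour Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated screening pipeline for REM sleep behaviour
    disorder (RBD) from a minimal polysomnography montage (one ECG, one EOG
    and one submentalis EMG channel, no EEG). Provides EDF signal and
    hypnogram input with three-state (W/NREM/REM) label mapping, per-modality
    filter banks, Pan-Tompkins QRS detection, a per-epoch heart-rate
    variability feature bank (time, frequency, nonlinear and Lorenz-plot
    regularity features), EOG and EMG staging features, random-forest sleep
    staging with subject-fold cross-validation, subject-level RBD metrics
    including the atonia index, random-forest RBD detection, Bland-Altman
    agreement analysis between metrics from manual and automatic staging, and
    a synthetic overnight cohort generator with ground truth for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
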