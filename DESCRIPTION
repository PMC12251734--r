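Package: cbeqc
Title: Movement-Quality Analysis for Chair-Based Exercise from Pose
    Landmarks and Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for assessing the execution quality of
    chair-based exercises in older adults from single-camera 2D pose
    landmarks and single-channel surface electromyography (sEMG).
    Computes vector-based joint angles from MediaPipe-layout keypoints,
    conditions sEMG through a 50 Hz notch, 20-450 Hz Butterworth bandpass
    and windowed RMS chain, extracts windowed time- and frequency-domain
    features (Welch power spectral density), classifies correct versus
    incorrect movement execution with a class-weighted RBF support vector
    machine under leave-one-out cross-validation, and summarises cohorts
    with paired statistics. A calibrated synthetic-cohort generator
    reproduces the statistical structure of published per-movement joint
    angle and sEMG amplitude distributions so the whole pipeline is
    testable without recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
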