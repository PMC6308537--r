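Package: ppwbp
Title: Cuffless Blood-Pressure Estimation from Pressure Pulse Waves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-subject calibration models for cuffless blood-pressure
    estimation from single-site radial pressure pulse wave (PPW) recordings.
    Provides zero-phase preprocessing (50 Hz low-pass, wavelet baseline
    removal), beat segmentation, detection of eleven fiducial landmarks per
    beat including a dicrotic-wave fallback rule, 21 morphological pulse-wave
    features plus pulse transit time (PTT), univariate least-squares
    calibration per feature, a multiparameter-fusion estimator (trimmed mean
    of the 21 single-feature predictions minus their standard deviation),
    three PTT baseline models, and a full evaluation suite (mean/standard
    difference of errors, cumulative percentages, BHS grading, AAMI verdict,
    Pearson correlation, Bland-Altman limits, between-model t-tests). A
    synthetic waveform and multi-day cohort generator with analytic landmark
    ground truth makes the whole pipeline testable without access to
    human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
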