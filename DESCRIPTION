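Package: mwppg
Title: Multi-Wavelength Photoplethysmography Fusion for Cuffless Blood
    Pressure Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating systolic and diastolic blood pressure from
    four-wavelength fingertip photoplethysmography (PPG). Implements the full
    pipeline: a synthetic multi-wavelength PPG cohort generator with
    morphology-linked blood-pressure labels, plain-text signal input/output,
    Butterworth band-pass preprocessing with quality screening and sliding-
    window segmentation, continuous wavelet transform (complex Gaussian
    'cgau1') scalogram images fused into a twelve-channel tensor, a compact
    channel-attention convolutional network with a two-layer bidirectional
    LSTM regressor trained with Adam on mean absolute error, and a device-
    validation evaluation harness (AAMI criterion, BHS grading, Bland-Altman
    limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
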