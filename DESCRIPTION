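Package: gaitsurf
Title: Walking-Surface Classification from Multi-Sensor IMU Gait Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for classifying the walking surface a person is
    moving over (flat pavement, stairs, slopes, banked surfaces, grass,
    cobblestone) from body-worn inertial measurement unit recordings.
    Provides zero-phase Butterworth smoothing, missing-value repair,
    non-overlapping window segmentation, per-fold min-max standardization,
    multi-sensor/multi-signal fusion into 2D network inputs, a 25-layer
    one-dimensional convolutional neural network with batch normalization
    and dropout trained by Adam with early stopping, trial-stratified
    6-fold cross-validation, weighted precision/recall/F1 reporting, greedy
    wrapper selection over signal groups and sensor placements, a window
    length sweep, and a synthetic multi-sensor gait simulator so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
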