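Package: strideseg
Title: Stride Segmentation for Foot-Worn Inertial Sensor Gait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments individual strides from continuous foot-worn inertial
    measurement unit (IMU) recordings. Implements a two-class hidden Markov
    model with Gaussian-mixture emissions: a strict left-right stride model
    and a wrap-around transition model are trained separately by Baum-Welch
    and flattened into a single segmenter whose Viterbi state path yields
    stride borders, snapped to minima of the sagittal-plane angular velocity.
    Includes the signal-processing front end (zero-phase Butterworth
    filtering, decimation, sliding-window features, per-bout
    standardization), a subsequence dynamic-time-warping baseline with
    template averaging, a tolerance-window evaluation framework
    (precision/recall/F1, walking-bout definition, bout-length groups,
    subject-wise cross-validation and grid search), and a synthetic gait
    generator producing labelled recordings with exact ground-truth borders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
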