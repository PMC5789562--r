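Package: qrscnn
Title: QRS Complex Detection with a Two-Level 1-D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects QRS complexes (R-peaks) in single-lead ECG recordings
    using a two-level one-dimensional convolutional neural network trained by
    back-propagation. Preprocessing uses only temporal difference and block
    averaging; a coarse (object-level) branch sees a whole-beat window of the
    averaged-difference signal while a fine (part-level) branch sees a
    QRS-scale window of the difference signal. Includes an annotated synthetic
    ECG generator with SNR-calibrated Gaussian noise injection, a sliding
    detector with refractory-period suppression and peak refinement, and the
    standard beat-detection evaluation protocol (sensitivity, positive
    predictivity rate, detection error rate, accuracy) with SNR degradation
    sweeps. All network forward and gradient computations are implemented in
    the package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
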