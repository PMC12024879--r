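Package: ppgfl
Title: Non-Invasive Blood Glucose Estimation from PPG Signals with Federated Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale, fully synthetic testbed for non-invasive blood glucose
    monitoring from photoplethysmography (PPG). Provides a synthetic PPG generator
    with a configurable glucose-to-morphology effect, continuous wavelet transform
    denoising with Donoho universal soft thresholding, adaptive cycle-based beat
    segmentation, a 13-feature morphological/spectral/nonlinear feature set, binary
    particle swarm optimization for feature selection, a federated-averaging
    simulator training a multi-task (regression + glucose-class) network, and
    evaluation via MARD, RMSE and Clarke error grid analysis.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
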