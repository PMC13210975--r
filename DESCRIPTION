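Package: coralspectra
Title: Spectral Filtering, Prototype Classification and State-Space
    Forecasting for Coral Health Monitoring
Version: 0.1.0
Authors@R:
    person("Coral", "Spectra Developers", email = "coralspectra@example.org",
           role = c("aut", "cre"))
Description: Tools for dual-domain coral-health monitoring at desk scale:
    a discrete-wavelet feature filter with learnable soft gating of
    sub-bands, a supervised-contrastive prototype classifier for the four
    coral health states (Healthy, Sub-healthy, Bleached, Dead) with
    calibration and separability diagnostics, a selective state-space
    forecaster of continuous health trajectories with a ConvLSTM baseline
    and Monte-Carlo-dropout uncertainty, physically motivated synthetic
    generators (turbid reef scenes, four-class coral blobs,
    degradation/recovery trajectories), and an evaluation harness
    (average precision, robustness scores, deployment energy/endurance
    arithmetic, experiment runner).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
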