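Package: bcilearn
Title: Longitudinal Learning Metrics for Sensorimotor-Rhythm Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal 2-class motor-imagery BCI training
    studies: Laplacian spatial filtering and Welch power spectral density
    extraction, canonical-variate feature selection, a Gaussian prototype
    classifier with rejection and evidence integration, frame-wise EOG artifact
    gating, between-/within-class learning metrics in the channel (Euclidean)
    and Riemannian covariance domains, trend and group statistics over training
    runs, a Cybathlon-style race-game simulator, and a synthetic EEG generator
    that emulates longitudinal skill-learning dynamics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
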