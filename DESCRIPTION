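Package: amacw
Title: Attention-Based Channel Weighting for EEG Bad-Channel Interpolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bad EEG channels from the remaining good channels
    using learnable channel embeddings and dot-product attention. Attention
    scores are mapped to signed interpolation weights by dividing each score
    by the sum of absolute scores, so anticorrelated channels contribute with
    negative weights. Training uses per-segment layer normalization with
    learnable per-channel gain and bias, and random channel masking to keep
    the weight distribution dispersed. Includes spherical-spline and
    Pearson-correlation baselines, an EEG preprocessing chain (average
    re-reference, 0.1-30 Hz band-pass, half-rate resampling, segmentation),
    a seeded generator of EEG-like synthetic recordings, and a paired MSE
    benchmark harness for 1-5 simultaneous bad channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
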