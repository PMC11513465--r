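Package: cdcrppg
Title: Remote Physiological Signal Recovery with Central Difference
    Convolutional Attention Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Camera-based recovery of pulse and respiration waveforms
    (remote photoplethysmography, rPPG) from facial video using an
    efficient spatio-temporal model: a dual-branch motion/appearance
    network built on temporal 3D central difference convolution with
    soft attention masks, trained with a robust Huber loss in a
    multi-task setting. Includes a synthetic facial-video simulator
    based on the dichromatic skin reflection model with respiratory
    sinus arrhythmia coupling, illumination-invariant normalized
    frame-difference preprocessing, spectral-peak heart-rate and
    respiration-rate estimation with Butterworth band-pass filtering,
    and agreement metrics (MAE, RMSE, Pearson r, Bland-Altman limits).
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
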