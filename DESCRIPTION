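Package: octsex
Title: Simulated Spectral-Domain OCT Imaging and CNN-Based Chick Sexing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for sexing day-old chicks from spectral-domain
    optical coherence tomography (SD-OCT) B-scans of the cloaca. Provides a
    parametric tissue-phantom generator with the male/female phallic-cone
    difference (three cones in males, two in females), an SD-OCT forward model
    and reconstruction chain (spectral interferogram synthesis, FFT envelope,
    scale-factor normalization, logarithmic compression to 8-bit), image
    preparation (enhancement, quality-based frame selection, augmentation,
    area-average resizing, leakage-aware train/test splits), a compact
    convolutional neural network classifier trained with Adam and early
    stopping, and a three-category evaluation surface (confusion matrix,
    per-class/macro/weighted precision, recall and F1, accuracy, learning
    curves, and an image-size ablation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
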