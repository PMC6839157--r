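Package: BUSseg
Title: Encoder-Decoder CNN Segmentation of Breast Ultrasound Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for semantic segmentation of breast lesions in
    ultrasound (BUS) images with series and directed-acyclic-graph (DAG)
    encoder-decoder convolutional neural networks. Provides a seeded
    synthetic speckle-phantom generator with benign (smooth elliptical)
    and malignant (spiculated, irregular) lesion morphologies, three CNN
    layer-graph builders (one series, two DAG variants with skip
    aggregation), stochastic-gradient-descent-with-momentum training with
    stratified splitting and k-fold cross-validation, the full
    segmentation metric suite (global and per-class accuracy, IoU,
    weighted IoU, Dice, boundary-F1), false-positive/false-negative
    error overlays, and pooled-variance t-test model comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
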