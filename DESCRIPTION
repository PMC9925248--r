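Package: lesionseg
Title: Melanoma Lesion Segmentation with Separable and Multi-Dilated Convolutions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An encoder-decoder segmentation pipeline for dermoscopic skin
    lesion images. Provides artifact-removal preprocessing (morphological
    closing and unsharp sharpening), a fixed 15-fold geometric augmentation
    registry, a UNet-style network built from depthwise-separable and
    multi-dilated convolution blocks with swish activations, pixel-level
    evaluation metrics (accuracy, Dice, Jaccard, sensitivity, specificity)
    with none/micro/macro averaging, and a seeded synthetic dermoscopy scene
    generator so the whole pipeline is testable without external data. The
    network layers, backpropagation and Adam optimiser are implemented in the
    package (C++ kernels via Rcpp), with naive pure-R convolution references
    serving as independent oracles.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
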