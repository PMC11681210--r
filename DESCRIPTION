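Package: thromboseg
Title: Attention-Gated Encoder-Decoder Segmentation of Deep Vein Thrombosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for binary segmentation of deep vein thrombosis (DVT) in
    grayscale CT venography slices. Implements an attention-gated
    encoder-decoder network assembled from residual, inception, dilated
    convolution, spatial pyramid pooling and attention-gate blocks, together
    with the surrounding pipeline: synthetic vascular phantom generation with
    pixel-exact ground truth, CLAHE/median/normalize/resize preprocessing,
    Adam training of a binary cross-entropy objective with early stopping,
    and a seven-metric evaluation suite (accuracy, precision,
    sensitivity/recall, specificity, Dice, IoU, BCE loss). The network engine
    (reverse-mode automatic differentiation with compiled convolution
    kernels) is self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    RNifti,
    optparse
Config/testthat/edition: 3
Collate:
    'thromboseg-package.R'
    'RcppExports.R'
    'conditions.R'
    'autodiff.R'
    'io.R'
    'phantom.R'
    'preprocess.R'
    'metrics.R'
    'blocks.R'
    'model.R'
    'train.R'
    'config.R'
    'cli.R'
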