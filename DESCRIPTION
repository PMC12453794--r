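Package: ggenet
Title: Teacher-Student Convolutional Networks with Attention-Map Knowledge Distillation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the GGENet family of convolutional image classifiers built
    from depthwise-separable residual blocks with global response normalization
    (GRN) and exact GELU activations, interleaved with channel-plus-spatial
    convolutional block attention. Provides adaptive knowledge distillation that
    transfers the three attention-module output maps from a large teacher network
    to a compact student through trained 1x1 channel adapters, with a dynamically
    weighted loss clamped to [0.25, 0.75], as well as classical logit distillation
    with an adaptive mixing weight. Includes a seeded synthetic fruit-spoilage
    image generator (six classes: fresh/rotten x apple/banana/orange), a
    stratified five-fold training and evaluation protocol with support-weighted
    precision/recall/F1 and one-vs-rest ROC AUC, Adam training with manual
    backpropagation through all layers, and a command-line interface. All
    convolution kernels are implemented in C++ via im2col and BLAS matrix
    products; no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    pROC,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
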