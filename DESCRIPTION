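Package: nestcae
Title: Semi-Supervised Convolutional Autoencoder Segmentation of
    Melanocyte Nests
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Segments nests of melanocytes (clusters of nevus cells) in
    hematoxylin-and-eosin stained histopathology images using a
    convolutional autoencoder trained with a three-phase semi-supervised
    protocol: unsupervised reconstruction pre-training on all images,
    supervised segmentation training with a frozen encoder and a reset
    decoder on the labeled subset, and whole-network fine-tuning at a
    reduced learning rate.  Includes image-level stratified splitting,
    128x128 patch extraction with class-dependent stride and rotation
    augmentation, whole-image mask inference by tile stitching, pixelwise
    Dice/sensitivity/specificity evaluation, and a seeded generator of
    H&E-like synthetic images with exact ground-truth masks.  The
    convolution, pooling and upsampling forward/backward passes are
    implemented in single-precision BLAS for CPU training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
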