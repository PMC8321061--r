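Package: polypseg
Title: Dilated Fully Convolutional Networks for Colonoscopy Polyp Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a multi-resolution dilated fully convolutional
    network (Dilated ResFCN) for pixel-wise segmentation of polyps in
    colonoscopy frames, together with the surrounding experimental
    machinery: a seeded phantom generator producing colonoscopy-like test
    images with exact ground-truth masks, the paired image/mask training
    augmentation pipeline (aspect-preserving rescale with random crop,
    rotation, scaling, thin-plate-spline deformation, corpus-statistics HSV
    jitter), video-grouped k-fold cross-validation with an Adam training
    schedule, rotation test-time augmentation, threshold-and-morphology
    post-processing, and a stratified evaluation suite (Dice, precision,
    recall, Jaccard, Hausdorff distance, with polyp-size and circularity
    strata). Receptive-field design diagnostics (effective dilated-kernel
    spans and valid-weight histograms) are included. All neural-network
    primitives are implemented in the package with Rcpp/RcppArmadillo
    kernels so the full pipeline runs on a single CPU at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
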