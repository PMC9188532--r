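Package: muscleseg
Title: Automatic Single-Muscle Segmentation of Thigh and Leg MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified deep-learning framework for automatic single-muscle
    segmentation of bilateral thigh and leg MRI cross-sections. A binary
    district classifier routes each 2D slice to one of two residual
    encoder-decoder segmentation networks (13 thigh classes, 7 leg classes,
    background included). The package implements the full pipeline from
    scratch: a synthetic limb-phantom generator with tunable fat-replacement
    severity, mask cleanup and anti-aliased down-sizing, four families of
    geometric data augmentation, class-balanced separation-border weight maps
    feeding a weighted cross-entropy loss, residual-block network
    construction with receptive-field bookkeeping, AMSGrad training with a
    plateau learning-rate schedule and hyperband hyperparameter search, and
    tree-structured inference over NIfTI volumes or PNG slices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
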