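Package: ratunet
Title: Residual U-Net Skull Stripping for Rat Brain MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Skull stripping (brain extraction) toolkit for coronal rat brain
    MR slices built around RU-Net, a U-shaped encoder-decoder segmentation
    network that combines batch-normalized pre-activation residual blocks with
    a pooling-index transmission mechanism (max-unpooling driven by the argmax
    indices stored during encoder max pooling). Provides NIfTI input/output
    with dataset-level z-score normalization, paired geometric augmentation
    (shear, rotation, zoom, horizontal reflection), soft Dice-loss training
    with Adam and a decaying learning-rate schedule, subject-level data splits
    and k-fold cross-validation, a segmentation evaluation suite (Dice,
    sensitivity, sensibility, Hausdorff and average Hausdorff distance in
    millimetres, paired t-tests), and a synthetic stroke-rat MR phantom
    generator so the whole pipeline is testable without access to animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
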