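Package: chondroseg
Title: Deep Residual Segmentation of Cartilage in Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic segmentation of thin cartilaginous structures
    (such as the embryonic nasal capsule) in large X-ray computed
    microtomography volumes. Implements a deep residual encoder-decoder
    convolutional network with deep supervision and SELU self-normalizing
    activations, trained slice-by-slice with Dice loss, an Adam/AMSgrad
    optimizer and a stochastic two-transform augmentation policy; k-fold
    cross-validation evaluation; inscribed-sphere local wall-thickness
    analysis of binary volumes; and a synthetic phantom generator producing
    micro-CT-like volumes with ground-truth shell masks so that every
    pipeline stage can be exercised at desk scale. Volumes are read and
    written as TIFF slice stacks or NIfTI-1 files with voxel-size metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
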