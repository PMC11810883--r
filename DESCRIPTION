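Package: sphereseg
Title: Spherical-Projection Ensemble Segmentation with Pixel-Wise
    Uncertainty
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Model-agnostic ensemble segmentation of 2D multi-parametric
    MRI slices via spherical image projection. A planar image is forward
    projected onto a sphere about each of k projection centers, segmented
    by a pluggable per-slice probabilistic predictor, and backward
    projected, yielding k co-registered probability maps. The ensemble is
    binarized with Otsu's global threshold and pixel-wise aleatoric
    uncertainty is quantified as the Shannon entropy of the k predictions.
    Includes the filtered-Dice/FTP/FTN uncertainty score with its three
    AUC components, segmentation metrics (accuracy, sensitivity,
    specificity, Dice, mean and 95th-percentile Hausdorff distance), a
    scaled-down reference U-Net and a test-time-augmentation baseline, and
    a synthetic contrast-enhancing-lesion phantom generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
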