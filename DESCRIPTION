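Package: whealmeter
Title: Automated Skin-Prick-Test Wheal Segmentation and Area Measurement
Version: 0.1.0
Authors@R:
    person("whealmeter", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for autonomous reading of skin prick tests (SPT) from
    photographs. Provides a synthetic scene and shape generator with known
    analytic ground truth, a fully convolutional network (VGG-16 encoder with
    FCN-8s style skip connections) for semantic wheal segmentation, reference
    tag calibrated pixel-to-area measurement, centroid-chord largest and
    perpendicular diameters with the circle (MA1) and ellipse (MA2)
    diameter-based area approximations, detection and confusion-matrix
    evaluation metrics, and Bland-Altman / Wilcoxon / ECDF method-agreement
    analyses comparing area-based and diameter-based wheal measurement
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
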