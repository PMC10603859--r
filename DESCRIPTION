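Package: caroseg
Title: Vessel-Wall Segmentation, Quantification and Reproducibility Analysis
    for 3D Carotid Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing 3D carotid ultrasound segmentations of the
    media-adventitia (MAB) and lumen-intima (LIB) boundaries around the
    carotid bifurcation. Provides contour geometry with shape-based
    inter-slice interpolation, Dice and Hausdorff reproducibility metrics,
    vessel-wall volume (VWV) and point-wise vessel-wall thickness (VWT)
    quantification with L-shaped 2D thickness maps, an agreement-statistics
    toolbox (normality-gated paired tests, two-way mixed absolute-agreement
    ICC, Pearson correlation, Bland-Altman repeatability), a two-channel
    U-Net segmentation network trained with an adaptive triple Dice loss,
    a synthetic carotid phantom generator with a virtual observer emulating
    repeated manual segmentation, and harnesses for inter-slice-distance
    reproducibility and train/test partition-strategy experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
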