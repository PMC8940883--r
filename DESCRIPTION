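Package: octbrain
Title: Attention ResNet Classification of Brain Tissue OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-class classification of optical coherence tomography (OCT)
    B-scans of brain tissue (normal cortex, glioblastoma, primary CNS
    lymphoma). Provides a Beer-Lambert single-scattering phantom simulator
    with gamma speckle and saturation artifacts, speckle reduction by
    registered 10-frame averaging, saturation-frame exclusion,
    standardization and bounded affine augmentation, a 14-layer
    pre-activation residual network with non-negative alpha-gated attention
    paths (implemented in-package with Rcpp convolution kernels), volume-wise
    stratified cross-validation with class-weighted SGD training and early
    stopping, and evaluation/interpretation tools: confusion matrices,
    one-vs-rest ROC/AUC with fold-averaged curves, grad-CAM heatmaps, and
    t-SNE embedding plots of the penultimate pooled features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    knitr
Config/testthat/edition: 3
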