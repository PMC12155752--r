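Package: mcmae
Title: Cross-Contrast Masked Autoencoding and Saliency Statistics for
    Multi-Contrast 3D Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of cross-contrast
    masked-reconstruction self-supervised pretraining for multi-contrast
    (T1-weighted, T2-weighted, FLAIR) 3D brain MRI, with downstream
    fine-tuning into a two-class parkinsonian-syndrome style discriminator,
    occlusion-sensitivity saliency maps with group-level permutation
    statistics (general linear model contrast, threshold-free cluster
    enhancement, max-statistic family-wise error control), and evaluation
    statistics (confusion-matrix metrics with bootstrap confidence
    intervals, ROC/AUC, the DeLong paired AUC test).  A seeded synthetic
    multi-contrast phantom generator provides reproducible cohorts with a
    controllable two-class structural effect, so every stage of the
    pipeline runs and is validated on a laptop-scale CPU budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
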