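Package: rdatrophy
Title: Regional Deep Atrophy Estimation from Longitudinal Deformation Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interpretable longitudinal atrophy estimation from medical image
    pairs and precomputed dense deformation fields. A trainable 3D U-Net
    attention model partitions the image into shrinkage, expansion and
    background regions; deformation-induced volume changes integrated over the
    attended regions are trained with self-supervised temporal losses (scan
    temporal order and relative interscan interval) so that the pooled change
    behaves as an atrophy-rate biomarker. Includes a synthetic longitudinal
    phantom generator with analytic ground-truth deformations, SSIM-based
    quality control, per-subject annualized rate estimation with age
    adjustment, group-difference statistics, and attention heatmap
    aggregation in a common template space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
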