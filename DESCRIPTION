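Package: sctflow
Title: Structurally-Constrained, Flow-Guided Cycle-Consistent GANs for
    MR-to-Synthetic-CT Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for generating synthetic CT (sCT) volumes from T2-weighted
    MR in an MR-only radiotherapy workflow. Implements four cycle-consistent
    adversarial objectives (plain CycleGAN, a windowed-SSIM structural
    constraint, a dense optical-flow interframe-consistency constraint, and
    their combination), a full preprocessing pipeline (body masking, intensity
    truncation, 16-bit normalization with invertible Hounsfield-unit recovery,
    slice trimming, bicubic resizing, site-based splitting), a Farneback
    polynomial-expansion dense optical-flow estimator with a bilinear warping
    operator, a compact convolutional network engine with residual generators
    and patch discriminators trained by Adam, Hounsfield-unit evaluation
    metrics (ME, MAE, PSNR) over body and organ masks, and a seeded synthetic
    pelvis phantom generator so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage,
    knitr,
    rmarkdown
Config/testthat/edition: 3
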