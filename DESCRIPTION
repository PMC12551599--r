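Package: ctmar
Title: Metal Artifact Reduction for CT with Latent-Diffusion Priors in a
    Normalized-MAR Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projection-domain metal artifact reduction (MAR) for 2D fan-beam
    CT. Implements a fan-beam forward projector and filtered backprojection,
    a polychromatic (beam-hardening plus photon-noise) simulator of paired
    clean/metal-corrupted dental phantom slices, classical LIMAR and
    normalized MAR (NMAR) with threshold or learned prior images, a
    vector-quantized autoencoder with a conditional latent denoising
    diffusion model that synthesizes artifact-reduced prior images, a
    learned metal-segmentation network replacing image-domain thresholding,
    a diffusion-based secondary artifact correction stage, and an
    evaluation/ablation harness (RMSE, PSNR, SSIM, ROI standard deviation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
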