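Package: retfusion
Title: Paired Translation Between Fluorescein Angiography and OCT
    Macular Thickness Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying paired image-to-image translation between
    mid-phase fluorescein angiography (FA) frames and color-coded OCT
    macular thickness maps in diabetic macular edema. Provides a seeded
    retinal phantom generator producing co-registered FA/OCT report pairs,
    a foveal-avascular-zone-based co-registration and cropping pipeline,
    a self-contained CPU implementation of the pix2pix conditional GAN
    (U-Net generator, patch-based discriminator, adversarial plus
    lambda-weighted L1 loss) with periodic generator checkpointing,
    Frechet-distance checkpoint selection, and a paired image quality
    suite (PSNR, SSIM, perceptual-hash Hamming distance, and a learned
    perceptual feature distance with spatial distance maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
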