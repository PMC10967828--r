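Package: octseg
Title: Hybrid Attention U-Net for Retinal Layer Segmentation in OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of the five sub-retinal regions of optical coherence
    tomography (OCT) B-scans with a hybrid attention U-Net: a five-level
    encoder-decoder whose two shallowest skip connections pass through
    edge-attention gates built on Sobel gradient operators and whose three
    deepest skips use max/average channel-pooled spatial attention, with
    residual skip features obtained by zeroing the max-pooled pixel of every
    pooling window.  Includes the full surrounding pipeline: a synthetic
    layered B-scan generator, pre-processing (crop, resize, Gaussian
    smoothing, CLAHE), a nine-transform mask-consistent augmentation stage, a
    from-scratch training engine with the AdaBound optimizer, plateau
    learning-rate reduction, early stopping, checkpoint restoration and
    k-fold cross-validation, and an evaluation suite of overlap and
    chance-corrected agreement statistics (Dice, boundary IoU, Cohen's kappa,
    Bennett S, Bangdiwala B, adjusted Rand index, Hamming loss).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
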