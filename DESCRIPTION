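Package: mrdenoise
Title: Self-Supervised and Unsupervised Denoising of Compressed-Sensing MR Images with No-Reference Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end desk-scale study of deep-learning denoising for
    compressed-sensing vessel-wall MR images. Generates synthetic brain-like
    phantoms with vessel wall, lumen, CSF, parenchyma and air regions; corrupts
    them with calibrated additive Gaussian noise (or Poisson-disk k-space
    undersampling with zero-filled reconstruction); trains a self-supervised
    U-Net denoiser on artificially corrupted aligned pairs and an unsupervised
    CycleGAN on unpaired noisy/clean domains; and evaluates both with a
    no-reference suite: region-of-interest noise and signal-to-noise ratio,
    blockwise noise maps, BRISQUE natural-scene statistics, radiomic texture
    and wavelet features, and Lin's concordance correlation reproducibility
    analysis. The convolutional-network engine (convolution, pooling,
    transposed convolution, batch and instance normalisation, Adam) is
    implemented with 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    RNifti,
    png,
    jsonlite,
    tools,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
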