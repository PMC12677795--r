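Package: fuseg
Title: PCA-Based MRI-PET Image Fusion and U-Net Brain Tumour Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage brain tumour segmentation for co-registered MRI/PET
    slice pairs. Stage one fuses the two modalities pixel-wise after a
    per-modality principal-component reconstruction (eigendecomposition of
    the row-standardised image stack covariance, computed through the Gram
    matrix or thin SVD); an eigenvector-weighted variant and a plain
    averaging baseline are included. Stage two segments the fused image with
    a five-level encoder-decoder convolutional network (3x3 convolutions,
    2x2 stride-2 max pooling and transpose convolutions, batch
    normalisation, sigmoid head) whose full-width layer plan carries
    122,480,513 trainable parameters; a width multiplier scales the network
    to desk size. The package also provides preprocessing (resizing,
    intensity normalisation, seeded augmentation, train/test splits),
    evaluation metrics (PSNR, SSIM, Dice, IoU, pixel accuracy), a seeded
    training loop with k-fold cross-validation, and a synthetic phantom
    generator producing co-registered pseudo-MRI/PET pairs with ground-truth
    tumour masks so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    RNifti,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
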