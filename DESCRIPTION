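Package: DermaFusion
Title: Two-Stream Multiscale Feature Fusion for Dermoscopy Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Seven-class dermoscopy skin-lesion classification with a two-stream
    convolutional network: a DenseNet-121 stream and a residual-augmented VGG-16
    stream fused by a multireceptive-field block (3x3/5x5/7x7 convolutions) with
    generalized-mean (GeM) spatial pooling and a softmax head. Includes the full
    preprocessing pipeline (black-hat hair removal with fast-marching inpainting,
    six-operation augmentation, class balancing, stratified 7:2:1 splitting), a
    CPU training loop with plateau learning-rate decay and early stopping,
    multiclass evaluation (macro/micro precision, recall, F1, one-vs-rest
    ROC/AUC, Grad-CAM), a thresholded classification service, and a seeded
    synthetic dermoscopy generator so the whole pipeline is testable at desk
    scale without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    EBImage,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
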