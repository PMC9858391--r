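Package: aclnet
Title: Attention CNN-LSTM Classification of Chest Radiographs with
    Marker-Controlled Watershed Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for three-class chest-radiograph
    classification. Images are preprocessed with Sobel gradients and
    marker-controlled watershed (MCW) segmentation to emphasise focal and
    diffuse opacities, then classified by a 28-layer hybrid network that
    combines convolutional feature extraction, a sigmoid attention gate and
    a single-step LSTM head (the "ACL" network), trained with stochastic
    gradient descent with momentum. Includes a seeded synthetic-radiograph
    generator with three separable disease-like classes, stratified
    train/test splitting at 70-30, 80-20 and 90-10 ratios, per-class
    sensitivity/specificity/precision/F-score and one-vs-rest ROC/AUC
    reporting, an attention/LSTM ablation runner, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
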