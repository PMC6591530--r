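Package: dwmacnn
Title: Patch-Based Deep Convolutional Networks for Diffuse White Matter
    Abnormality Detection in Neonatal T2 MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects diffuse white matter abnormality (DWMA) on T2-weighted
    neonatal brain MRI by classifying every white-matter voxel from the small
    2D image patch centred on it, using compact deep convolutional networks
    built for patch sizes 7, 9, 13 and 17. Ships a synthetic-phantom
    generator with ground-truth lesions and Rician noise, the
    intensity-threshold gold-standard labelling rule, patch extraction with
    subject-grouped splits, from-scratch CNN training (mini-batch SGD with
    Nesterov momentum, batch normalisation, Glorot initialisation, early
    stopping), linear-SVM and multilayer-perceptron baselines, and an
    evaluation harness reporting Dice, balanced accuracy, DWMA-to-brain
    ratio and Bland-Altman agreement under leakage-free cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
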