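Package: duralseg
Title: Segmentation and Classification of Dural Hemorrhages on Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An attention-based encoder-decoder framework for segmenting and
    classifying dural hemorrhages (subdural and epidural) on axial head-CT
    slices. Implements the full pipeline at desk scale: a seeded synthetic
    phantom generator that emulates crescent-shaped subdural and biconvex
    epidural lesions with pixel-accurate ground-truth masks; CT preprocessing
    (resizing, contrast-limited adaptive histogram equalization, gamma
    correction, normalization); stratified splitting and SMOTE image
    oversampling for class balance; a convolution-squeeze-excitation-residual
    (CSR) U-Net with spatial-attention-gated skip connections and a
    classification head, trained with a multi-task dice plus focal objective
    by Adam with plateau learning-rate decay; and the standard evaluation
    suite (dice, IoU, confusion-matrix metrics, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    utils,
    stats,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
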