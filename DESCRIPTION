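Package: auscultnet
Title: Attention-Based Classification of Pediatric Lung Auscultation Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to turn multi-site digital lung auscultation recordings into
    patient-level diagnostic predictions (control, pneumonia, wheezing disorder,
    bronchiolitis). Audio is converted to band-limited log-mel spectrograms and
    scored by a convolutional neural network with temporal attention pooling;
    per-site clip scores are aggregated by logistic regression into one
    prediction per patient, and four binary models are fused into a multinomial
    diagnostic classifier. Includes nested stratified cross-validation with
    ensemble external validation, Clopper-Pearson and DeLong confidence
    intervals, a clinical age/respiratory-rate baseline, the Mean-Attention
    Difference (MAD) statistic aligning model attention with annotated
    respiration phases, and a synthetic breath-sound simulator for end-to-end
    testing without clinical audio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    glmnet,
    pROC,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
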