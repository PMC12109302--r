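Package: multisess
Title: Multimodal Sleep Staging with Multi-Scale Convolution, Channel
    Attention and State-Space Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end automatic sleep stage classification from raw
    EEG and EOG polysomnography. Implements the MultiSEss architecture:
    per-modality multi-scale 1-D convolutional feature extraction,
    squeeze-and-excitation channel attention, and a state-space
    multimodal coupling recurrence that fuses the two signal streams
    before a fully connected softmax head. Includes a minimal EDF/EDF+
    reader and writer, preprocessing rules for Sleep-EDF style
    recordings (R&K to AASM label mapping, wake-margin trimming, 30 s
    epoch segmentation), a class-separable synthetic polysomnography
    generator, subject-wise k-fold cross-validation with weighted
    cross-entropy training, ablation variants, and the full evaluation
    metric set (accuracy, macro-F1, Cohen's kappa, sensitivity,
    specificity, precision, per-class precision).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
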