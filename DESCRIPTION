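Package: selfonn
Title: Self-Organized Operational Neural Networks for Transcranial
    Doppler Waveform Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of maximal cerebral blood-flow-velocity (CBFV)
    waveforms from transcranial Doppler (TCD) ultrasound into healthy and
    neurocritical (ICU) classes.  Implements 1D self-organized operational
    neural network (Self-ONN) layers, whose generative neurons learn a
    truncated Taylor-series non-linearity per kernel tap, together with
    residual (Self-ResNet18) and multi-head-attention (Self-ResAttentioNet18)
    architectures, maximal-velocity envelope extraction from Doppler
    spectrograms, signal-cut removal and fixed-length segmentation with
    overlap augmentation, session-independent k-fold cross-validation with
    an Adam training loop and plateau learning-rate schedule, weighted
    classification metrics with ROC/AUC, and a synthetic pulsatile CBFV
    cohort generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
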