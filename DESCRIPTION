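Package: afibnet
Title: Atrial Fibrillation Detection from Single-Lead ECG with Dual-Domain Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of short single-lead electrocardiograms into normal sinus
    rhythm, atrial fibrillation, other rhythm, and noisy recordings, in the
    PhysioNet/CinC 2017 storage dialect. Provides readers and writers for the
    MATLAB-v4/WFDB record format and CSV label files, a synthetic ECG generator with
    controllable rhythm statistics, the preprocessing chain (FIR bandpass filtering,
    standardization, log-spectrograms, Hamilton R-peak detection, beat segmentation,
    minority-class oversampling), a ten-operator stochastic augmentation pipeline,
    three neural architectures (ECG-DualNet with conditional batch normalization,
    the attention-based ECG-DualNet++, and the two-branch ECG-RCLSTM-Net) built on an
    internal reverse-mode automatic-differentiation engine, weighted cross-entropy
    training with an RAdam optimizer and a staged learning-rate schedule, and the
    challenge scoring system (binary F1, macro F1, CinC F1, AUROC/AUPRC) with a
    local leaderboard store.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
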