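Package: longidistill
Title: Self-Distilled CNN-LSTM Models for Longitudinal Microbiome Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies disease outcomes from longitudinal microbiome
    relative-abundance profiles with hybrid convolutional/recurrent sequence
    models trained under self-knowledge distillation. Provides padding
    strategies for subjects with missing time points (pad-in-sequence and
    pad-at-end with observation masks), optional principal-component feature
    reduction, branch-classifier and progressive (previous-epoch soft target)
    self-distillation training schemes, recurrent and sparse-autoencoder
    baselines, taxonomy-rank harmonization with discriminative fine-tuning
    for cross-study transfer, stratified cross-validated ROC-AUC/F1
    evaluation, a sensitivity analysis over truncated history, and a
    synthetic longitudinal cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    biomformat,
    yaml,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
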