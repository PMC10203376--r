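---
title: "Methods: self-distilled sequence models for longitudinal microbiome outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-distilled sequence models for longitudinal microbiome outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(longidistill)
```

## Overview

`longidistill` classifies subject-level disease outcomes from longitudinal
microbiome relative-abundance profiles. Each subject contributes a short
sequence of compositional taxon vectors sampled on a study-wide canonical
time grid, usually with visits missing. The package covers the full
pipeline: data assembly and padding, hybrid convolutional/recurrent
classifiers trained with self-knowledge distillation, cross-study transfer,
and cross-validated evaluation. All numerics, including the forward and
backward passes of the networks, are implemented in base R.

## Data model and padding strategies

An `abundance_table` (samples x taxa, rows summing to 1) and a
`sample_metadata` table (sample, subject, time point, outcome) are joined by
`assemble_cohort()` on an explicit canonical grid; off-grid samples and
conflicting subject labels are errors, never silently repaired.

Recurrent models need rectangular input, and two padding conventions are
provided:

* `pad_in_sequence()` places each observation at its canonical slot and
  zero-fills unobserved slots, preserving temporal spacing. Models train on
  these batches *without* masking: the zero vectors are seen by the
  recurrence.
* `pad_at_end()` compacts each subject's observations to the leading slots
  and zero-fills the suffix. Models train *with* the observation mask: at a
  masked slot the hidden and cell states carry through unchanged, so the
  final state equals the state at the subject's last observation.

A subject observed at weeks 0 and 52 on the grid (0, 4, 12, 52):

```{r padding}
tab <- suppressWarnings(abundance_table(
  rbind(c(0.29747, 0.00381, 0.00114, 0.18839),
        c(0.00168, 0.00839, 0.00839, 0.50269)),
  c("s1_w0", "s1_w52"),
  c("Ruminococcaceae", "Peptostreptococcaceae",
    "Alcaligenaceae", "Porphyromonadaceae")))
meta <- sample_metadata(data.frame(
  sample_id = c("s1_w0", "s1_w52"), subject_id = "s1",
  time_point = c(0, 52), label = "case"))
cohort <- assemble_cohort(tab, meta, canonical_grid = c(0, 4, 12, 52))

pad_in_sequence(cohort)$mask
pad_at_end(cohort, use_grid_length = TRUE)$mask
```

Optionally, `fit_pca()` / `apply_pca()` reduce the taxon axis to principal
components (study default: 300), fitted on training-fold rows only so no
information leaks across folds.

## Architectures

`ld_fit()` is the central fitting verb. Four architectures share one
training engine:

* **cnnlstm** — 1-D convolutions (ReLU, stride-2) over the taxon axis of
  each time point, weights shared across time, feeding an LSTM whose last
  hidden state is classified by a one-hidden-layer tanh MLP head.
* **lstm** — the LSTM alone on raw abundance vectors.
* **rnn** — a plain tanh recurrent cell in place of the LSTM.
* **ulstm** — a sparse autoencoder (logistic latent layer with a
  Bernoulli-KL sparsity penalty) trained unsupervised, its frozen codes fed
  per time point into an LSTM.

The LSTM uses the conventional tanh cell-output squashing by default;
`cell_activation = "sigmoid"` selects the logistic variant, as both
conventions appear in the literature. Mutually exclusive outcomes use a
softmax output with categorical cross-entropy; multi-label outcomes use
per-label sigmoids with Bernoulli cross-entropy.

Optimization is mini-batch adaptive-moment gradient descent with
bias-corrected first and second moments; all gradients are derived and
implemented by hand and verified against finite differences.

## Self-knowledge distillation

Two schemes reuse the model's own knowledge during training; neither adds
any cost at prediction time.

**Branch-classifier distillation** (`distill = "fd"`) attaches shallow
classifiers to intermediate representations (the last time point's features
and the final hidden state). Each branch is trained with the hard labels,
pulled toward the gradient-detached main classifier's distribution via
`kl_divergence(branch, main)`, and penalized by `feature_l2()` for
penultimate-weight mismatch with the main head; the three terms are weighted
by `fd_weights`. The branches act as deep supervision and are discarded
after training.

**Progressive self-distillation** (`distill = "sd"`) blends hard targets
with the model's previous-epoch predictions as soft targets,
`(1 - alpha_t) CE(y, p) + alpha_t CE(p_prev, p)`, with the linear ramp
`alpha_t = alpha_T * t / T` from `distill_schedule()`.

Both schemes reduce exactly to plain training when switched off (all
`fd_weights` zero, or `alpha_T = 0`): the weight initialization and
shuffling streams are separated so the reductions are bit-identical.

```{r fit}
syn <- generate(synth_config(n_subjects = 40, n_features = 20, seed = 1))
coh <- assemble_cohort(syn$table, syn$meta, syn$canonical_grid)
fit <- ld_fit(pad_in_sequence(coh), model = "cnnlstm", distill = "fd",
              config = net_config(hidden_size = 8, head_hidden = 8,
                                  epochs = 5, batch_size = 16,
                                  conv_layers = list(list(out_channels = 4,
                                                          kernel_size = 5,
                                                          stride = 2))),
              seed = 1)
fit
head(predict(fit, pad_in_sequence(coh)))
```

## Cross-study transfer

Two studies rarely share a feature space. `read_taxonomy_map()` parses
lineages, `aggregate_to_rank()` sums abundances at a chosen rank (conserving
row totals), and `harmonize()` intersects the two studies' group
inventories, yielding a shared, lexicographically ordered feature space plus
a report of dropped groups. `transfer_fit()` then loads a source model's
body, replaces the head by a freshly initialized concat-pooling head (mean,
max and last hidden state), and fine-tunes with discriminative per-block
learning rates (`discriminative_lrs()`: each block toward the input trains
at the rate divided by `decay`) and gradual unfreezing
(`unfreeze_schedule()`: one block per epoch, output first).

## Evaluation

`cross_validate()` implements the study protocol: subject-level stratified
k-fold splits (`kfold_split()`), per-fold training and held-out scoring by
rank-based (midrank) ROC-AUC — one-vs-rest macro average for multi-class,
per-label mean for multi-label — and macro F1, `tp / (tp + (fp + fn) / 2)`.
`evaluate_last_timepoint()` adds the two last-visit protocols (drop subjects
unobserved at the final slot, or score each subject from its own last
observation), and `sensitivity_over_history()` re-runs the cross-validation
with each subject truncated to its first h observations to quantify how much
history the model needs.

```{r cv}
cv <- cross_validate(coh, model = "lstm", k = 2, seed = 1,
                     config = net_config(hidden_size = 8, head_hidden = 8,
                                         epochs = 3, batch_size = 16))
cv
```

## Synthetic cohorts

`generate()` draws cohorts from an explicit generative model: Dirichlet
baseline compositions (concentration 0.5 for sparse, microbiome-like
profiles), a class-dependent multiplicative log-linear drift on a fixed
fraction of signal taxa, log-normal sampling noise, renormalization, and
independent dropping of non-initial visits. The generator's defaults are
treated as fixed study conditions; `effect_size = 0` yields a null cohort on
which every model should score at chance. `make_paired_studies()` creates
two cohorts with partially overlapping phylum inventories as the transfer
fixture, and `write_cohort_tsv()` emits the loader-compatible TSV trio.

## Problem sizes in the test suite

The shipped tests verify paper-scale *mechanisms* at reduced scale chosen by
pilot sizing of the networks only (the data generator is never adjusted):
small hidden sizes and epoch counts wherever exactness, not accuracy, is
asserted, and a mid-sized two-layer convolutional body where the comparative
claim about branch distillation is tested, since deep supervision needs a
body deep enough to supervise.
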