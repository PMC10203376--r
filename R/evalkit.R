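## Cross-validated evaluation: subject-level stratified k-fold splitting,
## rank-based ROC-AUC, F1, and the sensitivity analysis over truncated
## history.

#' Subject-level k-fold cross-validation splits
#'
#' Splits subjects (never individual samples) into k disjoint folds of
#' near-equal size. In stratified mode each outcome class is dealt
#' round-robin across folds so per-fold label frequencies stay within one
#' subject of the cohort's.
#'
#' @param labels subject-level outcome labels (factor or vector), or a
#'   `longitudinal_cohort` whose primary label is used.
#' @param k number of folds.
#' @param seed RNG seed; identical seeds give identical splits.
#' @param stratified balance label frequencies per fold.
#' @return list of k elements, each `list(train = <indices>, valid =
#'   <indices>)`.
#' @export
kfold_split <- function(labels, k = 10, seed = 1L, stratified = TRUE) {
  if (inherits(labels, "longitudinal_cohort")) {
    lab <- cohort_labels(labels)
    if (is.matrix(lab)) lab <- factor(lab[, 1])  # stratify on primary label
    labels <- lab
  }
  labels <- as.factor(labels)
  n <- length(labels)
  if (k > n) stop("k exceeds the number of subjects")
  fold_of <- integer(n)
  set.seed(seed)
  if (stratified) {
    start <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  } else {
    fold_of <- rep(seq_len(k), length.out = n)[sample.int(n)]
  }
  splits <- lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), valid = which(fold_of == f)))
  if (stratified) {
    for (f in seq_len(k)) {
      miss <- setdiff(levels(labels), unique(as.character(labels[splits[[f]]$train])))
      if (length(miss) > 0)
        warning(sprintf("class '%s' absent from the training part of fold %d",
                        miss[1], f))
    }
  }
  splits
}

#' F1 score from confusion counts
#'
#' \eqn{F_1 = 2\,\frac{\mathrm{precision}\cdot\mathrm{recall}}
#' {\mathrm{precision}+\mathrm{recall}} = \frac{tp}{tp + (fp + fn)/2}}.
#' Defined as 0 (with a warning) when tp + fp + fn = 0.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts;
#'   `tp` may also be a named vector/list carrying all three.
#' @return scalar in \[0, 1\].
#' @export
f1_score <- function(tp, fp = NULL, fn = NULL) {
  if (is.null(fp) && (is.list(tp) || length(tp) > 1)) {
    fp <- tp[["fp"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  if (tp + fp + fn == 0) {
    warning("no positive decisions or labels; F1 defined as 0")
    return(0)
  }
  tp / (tp + (fp + fn) / 2)
}

auc_binary <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) {
    warning("ROC-AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Rank-based ROC-AUC
#'
#' The probability that a randomly drawn positive outscores a randomly drawn
#' negative, with ties counted half (midrank formulation). Multi-class
#' scores are averaged one-vs-rest over classes (`"macro_ovr"`);
#' multi-label scores are averaged over labels (`"per_label_mean"`).
#' Classes or labels with a single observed value are undefined and dropped
#' from the average with a warning.
#'
#' @param scores numeric vector (binary) or matrix with one column per
#'   class/label.
#' @param labels binary vector/factor, class factor, or 0/1 label matrix.
#' @param mode `"binary"`, `"macro_ovr"` or `"per_label_mean"`.
#' @return scalar AUC (NA when undefined everywhere).
#' @export
roc_auc <- function(scores, labels, mode = c("binary", "macro_ovr",
                                             "per_label_mean")) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    pos <- if (is.factor(labels)) labels == levels(labels)[2]
           else as.logical(labels %in% c(1, TRUE, "1"))
    return(auc_binary(as.numeric(scores), pos))
  }
  scores <- as.matrix(scores)
  if (mode == "macro_ovr") {
    labels <- as.factor(labels)
    per <- vapply(seq_along(levels(labels)), function(ci)
      auc_binary(scores[, ci], labels == levels(labels)[ci]), numeric(1))
  } else {
    labels <- as.matrix(labels)
    per <- vapply(seq_len(ncol(labels)), function(li)
      auc_binary(scores[, li], labels[, li] == 1), numeric(1))
  }
  if (all(is.na(per))) return(NA_real_)
  mean(per, na.rm = TRUE)
}

# macro F1 from hard predictions (one-vs-rest per class), or per-label mean
# of binary F1 at threshold 0.5 in multi-label mode
macro_f1 <- function(probs, labels, multi_label, label_levels) {
  if (multi_label) {
    pred <- probs >= 0.5
    truth <- as.matrix(labels) == 1
    per <- vapply(seq_len(ncol(truth)), function(li) {
      tp <- sum(pred[, li] & truth[, li])
      fp <- sum(pred[, li] & !truth[, li])
      fn <- sum(!pred[, li] & truth[, li])
      if (tp + fp + fn == 0) return(NA_real_)
      f1_score(tp, fp, fn)
    }, numeric(1))
    return(mean(per, na.rm = TRUE))
  }
  pred <- label_levels[max.col(probs)]
  truth <- as.character(labels)
  per <- vapply(label_levels, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp + fp + fn == 0) return(NA_real_)
    f1_score(tp, fp, fn)
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

metrics_auc_mode <- function(multi_label, n_levels) {
  if (multi_label) "per_label_mean" else if (n_levels == 2) "macro_ovr"
  else "macro_ovr"
}

compute_fold_metrics <- function(probs, labels, multi_label, label_levels) {
  auc <- suppressWarnings(
    roc_auc(probs, labels, mode = if (multi_label) "per_label_mean"
                                  else "macro_ovr"))
  f1 <- macro_f1(probs, labels, multi_label, label_levels)
  list(auc = auc, f1 = f1, n_eval = if (is.matrix(labels)) nrow(labels)
                                    else length(labels))
}

#' Evaluate a fitted model at the subjects' last time points
#'
#' Two evaluation protocols over a held-out batch: `"padded_last_slot"`
#' removes subjects not observed at the final canonical slot before scoring
#' (the padded-model convention), while `"last_available"` keeps every
#' subject and scores each from its own last observation.
#'
#' @param model an `ld_model`.
#' @param batch a held-out `padded_batch`.
#' @param protocol `"padded_last_slot"` or `"last_available"`.
#' @return list with `auc`, `f1`, `n_eval` and the retained subject ids.
#' @export
evaluate_last_timepoint <- function(model, batch,
                                    protocol = c("padded_last_slot",
                                                 "last_available")) {
  protocol <- match.arg(protocol)
  keep <- if (protocol == "padded_last_slot")
            which(batch$mask[, ncol(batch$mask)] == 1)
          else seq_len(nrow(batch$mask))
  if (length(keep) == 0) stop("no subjects retained under protocol ", protocol)
  sub <- subset_batch(batch, keep)
  probs <- predict(model, sub, type = "prob")
  out <- compute_fold_metrics(probs, sub$labels, sub$multi_label,
                              sub$label_levels)
  out$retained <- sub$subject_ids
  message(sprintf("protocol %s: retained %d of %d subjects", protocol,
                  length(keep), nrow(batch$mask)))
  out
}

#' Cross-validated training and evaluation
#'
#' The study protocol: subjects are split into k stratified folds; per fold
#' the model is trained on the remaining folds (with PCA, when enabled,
#' fitted on the training fold's observed rows only) and scored on the held
#' out fold by macro ROC-AUC and macro F1. Fold metrics are aggregated to
#' mean and standard deviation.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param model,distill,config,seed passed to [ld_fit()]; fold fits derive
#'   their seeds from `seed`.
#' @param strategy `"pad_in_sequence"` or `"pad_at_end"`.
#' @param pca logical; project features onto principal components fitted per
#'   training fold.
#' @param n_components retained components when `pca` is on.
#' @param k number of folds.
#' @param stratified stratify the split on the primary label.
#' @param protocol subject-retention rule passed to the fold evaluation:
#'   `"all"` keeps every held-out subject; `"padded_last_slot"` drops
#'   subjects unobserved at the final canonical slot.
#' @return an object of class `ld_cv`: per-fold metrics, their summary, and
#'   the run settings.
#' @export
cross_validate <- function(cohort, model = "cnnlstm", distill = "none",
                           strategy = c("pad_in_sequence", "pad_at_end"),
                           pca = FALSE, n_components = 300, k = 10,
                           seed = 1L, config = net_config(),
                           stratified = TRUE,
                           protocol = c("all", "padded_last_slot")) {
  strategy <- match.arg(strategy)
  protocol <- match.arg(protocol)
  batch <- if (strategy == "pad_in_sequence") pad_in_sequence(cohort)
           else pad_at_end(cohort)
  splits <- kfold_split(cohort, k = k, seed = seed, stratified = stratified)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr_b <- subset_batch(batch, splits[[f]]$train)
    va_b <- subset_batch(batch, splits[[f]]$valid)
    if (pca) {
      mapping <- fit_pca(observed_rows(tr_b), n_components = n_components)
      tr_b <- apply_pca(mapping, tr_b)
      va_b <- apply_pca(mapping, va_b)
    }
    fit <- ld_fit(tr_b, model = model, distill = distill, config = config,
                  seed = seed + 101L * f)
    if (protocol == "padded_last_slot") {
      keep <- which(va_b$mask[, ncol(va_b$mask)] == 1)
      if (length(keep) == 0) stop("no subjects retained in fold ", f)
      va_b <- subset_batch(va_b, keep)
    }
    probs <- predict(fit, va_b, type = "prob")
    mt <- compute_fold_metrics(probs, va_b$labels, va_b$multi_label,
                               va_b$label_levels)
    rows[[f]] <- data.frame(fold = f, auc = mt$auc, f1 = mt$f1,
                            n_eval = mt$n_eval)
  }
  folds <- do.call(rbind, rows)
  structure(list(
    folds = folds,
    summary = c(auc_mean = mean(folds$auc, na.rm = TRUE),
                auc_sd = stats::sd(folds$auc, na.rm = TRUE),
                f1_mean = mean(folds$f1, na.rm = TRUE),
                f1_sd = stats::sd(folds$f1, na.rm = TRUE)),
    settings = list(model = model, distill = distill, strategy = strategy,
                    pca = pca, n_components = n_components, k = k,
                    seed = seed, stratified = stratified,
                    protocol = protocol,
                    auc_mode = if (cohort$multi_label) "per_label_mean"
                               else "macro_ovr", f1_mode = "macro")),
    class = "ld_cv")
}

#' @export
print.ld_cv <- function(x, ...) {
  s <- x$settings
  cat(sprintf("%d-fold CV: %s / %s / %s%s (AUC: %s, F1: macro)\n",
              s$k, toupper(s$model), s$distill, s$strategy,
              if (s$pca) sprintf(" / PCA(%d)", s$n_components) else "",
              s$auc_mode))
  cat(sprintf("  AUC %.3f +/- %.3f   F1 %.3f +/- %.3f\n",
              x$summary["auc_mean"], x$summary["auc_sd"],
              x$summary["f1_mean"], x$summary["f1_sd"]))
  invisible(x)
}

#' Sensitivity of performance to the amount of history
#'
#' For each horizon h, every subject is truncated to its first h observed
#' time points, the batch is re-padded, and the full cross-validation is
#' re-run; the resulting mean and standard deviation of AUC and F1 quantify
#' how much past microbiome history the model needs.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param horizons integer vector of history lengths (>= 1).
#' @param ... passed to [cross_validate()].
#' @return data.frame with one row per horizon: `horizon`, `auc_mean`,
#'   `auc_sd`, `f1_mean`, `f1_sd`.
#' @export
sensitivity_over_history <- function(cohort, horizons, ...) {
  if (any(horizons < 1)) stop("horizons must be >= 1")
  rows <- lapply(horizons, function(h) {
    cv <- cross_validate(truncate_history(cohort, h), ...)
    data.frame(horizon = h,
               auc_mean = cv$summary["auc_mean"], auc_sd = cv$summary["auc_sd"],
               f1_mean = cv$summary["f1_mean"], f1_sd = cv$summary["f1_sd"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}
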