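# Evaluation: splitting, F1, ROC-AUC, last-time-point protocols,
# cross-validation, sensitivity over truncated history.

test_that("kfold_split partitions subjects with near-equal folds", {
  labs <- rep(c("a", "b"), each = 10)
  sp <- kfold_split(labs, k = 10, seed = 1)
  expect_length(sp, 10)
  sizes <- vapply(sp, function(s) length(s$valid), integer(1))
  expect_true(all(sizes == 2))
  all_valid <- sort(unlist(lapply(sp, `[[`, "valid")))
  expect_equal(all_valid, 1:20)  # disjoint and exhaustive
  for (s in sp) {
    expect_length(intersect(s$train, s$valid), 0)
    expect_equal(sort(c(s$train, s$valid)), 1:20)
  }
})

test_that("kfold_split is seed-deterministic and stratifies 60/40", {
  labs <- factor(rep(c("x", "y"), c(60, 40)))
  a <- kfold_split(labs, k = 5, seed = 9)
  b <- kfold_split(labs, k = 5, seed = 9)
  expect_identical(a, b)
  d <- kfold_split(labs, k = 5, seed = 10)
  expect_false(identical(a, d))
  for (s in a) {
    tab <- table(labs[s$valid])
    expect_equal(unname(tab["x"]), 12)  # 60/5 exactly
    expect_equal(unname(tab["y"]), 8)
  }
  expect_error(kfold_split(labs, k = 101), "k exceeds")
})

test_that("f1_score closed forms and the degenerate case", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(0, 5, 5), 0)
  expect_equal(f1_score(5, 5, 5), 0.5)
  expect_equal(f1_score(c(tp = 8, fp = 2, fn = 4)), 8 / (8 + 3))
  expect_warning(z <- f1_score(0, 0, 0), "defined as 0")
  expect_equal(z, 0)
})

test_that("f1_score equals 2PR/(P+R) on random counts to 1e-12", {
  set.seed(91)
  for (rep in 1:200) {
    tp <- sample(1:500, 1); fp <- sample(0:500, 1); fn <- sample(0:500, 1)
    expect_lt(abs(f1_score(tp, fp, fn) - oracle_f1(tp, fp, fn)), 1e-12)
  }
})

test_that("roc_auc has its closed forms", {
  # perfect separation
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  # all-tied scores: exactly 0.5 by the midrank convention
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # invariance under monotone transformation of the scores
  set.seed(92)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(s, y), roc_auc(qlogis(s), y), tolerance = 1e-12)
  expect_warning(one <- roc_auc(c(0.1, 0.9), c(1, 1)), "only one class")
  expect_true(is.na(one))
})

test_that("roc_auc on random scores sits at the null value", {
  set.seed(93)
  n <- 10000
  s <- runif(n); y <- rbinom(n, 1, 0.5)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.02)
})

test_that("binary roc_auc agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(94)
  for (rep in 1:5) {
    y <- rbinom(60, 1, 0.5)
    s <- runif(60) + 0.4 * y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("macro and per-label AUC average the one-vs-rest columns", {
  set.seed(95)
  y <- factor(sample(c("a", "b", "c"), 40, replace = TRUE))
  S <- matrix(runif(120), 40, 3)
  per <- vapply(1:3, function(ci)
    roc_auc(S[, ci], as.numeric(y == levels(y)[ci])), numeric(1))
  expect_equal(roc_auc(S, y, mode = "macro_ovr"), mean(per), tolerance = 1e-12)
  Y <- matrix(rbinom(80, 1, 0.4), 40, 2)
  S2 <- matrix(runif(80), 40, 2)
  per2 <- vapply(1:2, function(li) roc_auc(S2[, li], Y[, li]), numeric(1))
  expect_equal(roc_auc(S2, Y, mode = "per_label_mean"), mean(per2),
               tolerance = 1e-12)
})

test_that("last-time-point protocols retain the right subjects", {
  coh <- small_cohort(n = 30, Fk = 8, seed = 96, missing_rate = 0.4)
  batch <- pad_in_sequence(coh)
  fit <- ld_fit(batch, model = "lstm", config = tiny_net(epochs = 2), seed = 1)
  n_last <- sum(batch$mask[, ncol(batch$mask)] == 1)
  expect_message(
    padded <- evaluate_last_timepoint(fit, batch, "padded_last_slot"),
    sprintf("retained %d of 30 subjects", n_last))
  expect_equal(padded$n_eval, n_last)
  expect_length(padded$retained, n_last)
  expect_message(
    all_s <- evaluate_last_timepoint(fit, batch, "last_available"),
    "retained 30 of 30 subjects")
  expect_equal(all_s$n_eval, 30)
  expect_true(is.finite(all_s$auc) && all_s$auc >= 0 && all_s$auc <= 1)
})

test_that("cross_validate summarizes exactly its fold table", {
  coh <- small_cohort(n = 30, Fk = 8, seed = 97)
  cv <- cross_validate(coh, model = "lstm", k = 3, seed = 5,
                       config = tiny_net(epochs = 2))
  expect_s3_class(cv, "ld_cv")
  expect_equal(nrow(cv$folds), 3L)
  expect_equal(cv$folds$fold, 1:3)
  expect_equal(unname(cv$summary["auc_mean"]), mean(cv$folds$auc))
  expect_equal(unname(cv$summary["auc_sd"]), sd(cv$folds$auc))
  expect_equal(unname(cv$summary["f1_mean"]), mean(cv$folds$f1))
  expect_equal(sum(cv$folds$n_eval), 30)
  expect_output(print(cv), "3-fold CV: LSTM")
  # repeat with the same seed is identical
  cv2 <- cross_validate(coh, model = "lstm", k = 3, seed = 5,
                        config = tiny_net(epochs = 2))
  expect_identical(cv$folds, cv2$folds)
})

test_that("cross_validate supports the PCA and padded-last-slot options", {
  coh <- small_cohort(n = 30, Fk = 10, seed = 98, missing_rate = 0.3)
  cv <- cross_validate(coh, model = "lstm", k = 2, seed = 3,
                       config = tiny_net(epochs = 2),
                       pca = TRUE, n_components = 4,
                       protocol = "padded_last_slot")
  batch <- pad_in_sequence(coh)
  expect_lt(sum(cv$folds$n_eval), 30)
  expect_equal(sum(cv$folds$n_eval),
               sum(batch$mask[, ncol(batch$mask)] == 1))
  expect_true(cv$settings$pca)
  expect_equal(cv$settings$auc_mode, "macro_ovr")
})

test_that("full-horizon sensitivity reproduces the plain CV row", {
  coh <- small_cohort(n = 24, Fk = 8, seed = 99, missing_rate = 0)
  Tn <- length(coh$canonical_grid)
  sens <- sensitivity_over_history(coh, horizons = c(1, Tn), model = "lstm",
                                   k = 2, seed = 4,
                                   config = tiny_net(epochs = 2))
  expect_equal(nrow(sens), 2L)
  expect_equal(sens$horizon, c(1, Tn))
  cv <- cross_validate(coh, model = "lstm", k = 2, seed = 4,
                       config = tiny_net(epochs = 2))
  expect_equal(sens$auc_mean[2], unname(cv$summary["auc_mean"]),
               tolerance = 1e-12)
  expect_equal(sens$f1_mean[2], unname(cv$summary["f1_mean"]),
               tolerance = 1e-12)
  expect_error(sensitivity_over_history(coh, horizons = 0), ">= 1")
})
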