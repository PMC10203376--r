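# Distillation losses, schedules and the training loop.

test_that("cross_entropy closed forms", {
  y <- diag(3)
  # uniform prediction over K classes: loss = log(K)
  expect_equal(cross_entropy(y, matrix(1 / 3, 3, 3)), log(3), tolerance = 1e-12)
  # perfect prediction: only the clamp keeps it off zero
  expect_equal(cross_entropy(y, y), -log(1 - 1e-7), tolerance = 1e-12)
  expect_error(cross_entropy(y, matrix(0.5, 3, 2)), "shapes differ")
  expect_error(cross_entropy(matrix(0, 0, 2), matrix(0, 0, 2)), "empty batch")
  # unit sample weights match the unweighted mean
  p <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(cross_entropy(diag(2), p, sample_weights = c(1, 1)),
               cross_entropy(diag(2), p), tolerance = 1e-14)
})

test_that("cross_entropy and kl_divergence match the loop oracles", {
  set.seed(61)
  for (rep in 1:20) {
    m <- sample(2:8, 1); K <- sample(2:5, 1)
    y <- t(apply(matrix(rexp(m * K), m), 1, function(r) r / sum(r)))
    p <- t(apply(matrix(rexp(m * K), m), 1, function(r) r / sum(r)))
    q <- t(apply(matrix(rexp(m * K), m), 1, function(r) r / sum(r)))
    expect_lt(abs(cross_entropy(y, p) - oracle_cross_entropy(y, p)), 1e-10)
    expect_lt(abs(kl_divergence(p, q) - oracle_kl(p, q)), 1e-10)
    expect_gte(kl_divergence(p, q), -1e-12)
  }
})

test_that("kl_divergence is zero at equality and asymmetric", {
  p <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2, byrow = TRUE)
  q <- matrix(c(0.5, 0.5, 0.1, 0.9), 2, 2, byrow = TRUE)
  expect_equal(kl_divergence(p, p), 0, tolerance = 1e-12)
  expect_gt(abs(kl_divergence(p, q) - kl_divergence(q, p)), 1e-6)
  expect_error(kl_divergence(p, matrix(0.5, 2, 3)), "shapes differ")
})

test_that("feature_l2 closed form and shape guard", {
  A <- matrix(1:6, 2, 3)
  expect_equal(feature_l2(A, A), 0)
  B <- A + 2
  expect_equal(feature_l2(A, B), 4)
  set.seed(62)
  C <- matrix(rnorm(6), 2, 3); D <- matrix(rnorm(6), 2, 3)
  expect_lt(abs(feature_l2(C, D) - oracle_feature_l2(C, D)), 1e-12)
  expect_error(feature_l2(A, matrix(0, 3, 2)), "shapes differ")
})

test_that("first_distillation_loss composes its terms with the weights", {
  set.seed(63)
  y <- diag(2)[c(1, 2, 1), ]
  main <- t(apply(matrix(rexp(6), 3), 1, function(r) r / sum(r)))
  br <- lapply(1:2, function(i)
    t(apply(matrix(rexp(6), 3), 1, function(r) r / sum(r))))
  W_M <- matrix(rnorm(12), 3, 4)
  W_S <- lapply(1:2, function(i) matrix(rnorm(12), 3, 4))
  w <- c(0.3, 0.7, 2)
  out <- first_distillation_loss(main, br, y, weights = w,
                                 W_M = W_M, W_S_list = W_S)
  want_terms <- c(
    main_ce = cross_entropy(y, main),
    branch_ce = cross_entropy(y, br[[1]]) + cross_entropy(y, br[[2]]),
    branch_kl = kl_divergence(br[[1]], main) + kl_divergence(br[[2]], main),
    feature_l2 = feature_l2(W_M, W_S[[1]]) + feature_l2(W_M, W_S[[2]]))
  expect_equal(out$terms, want_terms, tolerance = 1e-12)
  expect_equal(out$total,
               want_terms[["main_ce"]] + sum(w * want_terms[-1]),
               tolerance = 1e-12)
  # zero weights reduce the total to the plain cross-entropy
  red <- first_distillation_loss(main, br, y, weights = c(0, 0, 0),
                                 W_M = W_M, W_S_list = W_S)
  expect_equal(red$total, want_terms[["main_ce"]], tolerance = 1e-12)
  expect_error(first_distillation_loss(main, list(), y), "at least one branch")
})

test_that("the soft-target schedule is exactly linear and bounded", {
  sch <- distill_schedule(alpha_T = 0.8, T_total = 100)
  tt <- 0:100
  expect_equal(alpha_at(sch, tt), 0.8 * tt / 100)
  expect_equal(alpha_at(sch, 0), 0)
  expect_equal(alpha_at(sch, 100), 0.8)
  expect_true(all(diff(alpha_at(sch, tt)) > 0))
  expect_error(alpha_at(sch, -1), "outside")
  expect_error(alpha_at(sch, 101), "outside")
  expect_error(distill_schedule(alpha_T = 1.2), "alpha_T")
  expect_error(distill_schedule(T_total = 0), "T_total")
})

test_that("psk_loss reduces to its two endpoints", {
  set.seed(64)
  y <- diag(2)[c(1, 2, 2), ]
  p <- t(apply(matrix(rexp(6), 3), 1, function(r) r / sum(r)))
  teach <- t(apply(matrix(rexp(6), 3), 1, function(r) r / sum(r)))
  expect_equal(psk_loss(y, p, teach, 0), cross_entropy(y, p), tolerance = 1e-14)
  expect_equal(psk_loss(y, p, teach, 1), cross_entropy(teach, p),
               tolerance = 1e-14)
  # teacher equal to the prediction at alpha 1: the prediction's own entropy
  expect_equal(psk_loss(y, p, p, 1), cross_entropy(p, p), tolerance = 1e-14)
  mid <- psk_loss(y, p, teach, 0.4)
  expect_equal(mid, 0.6 * cross_entropy(y, p) + 0.4 * cross_entropy(teach, p),
               tolerance = 1e-14)
  expect_error(psk_loss(y, p, NULL, 0.5), "teacher cache is empty")
  expect_error(psk_loss(y, p, teach[1:2, ], 0.5), "every sample")
})

test_that("autoencoder_loss terms follow their definitions", {
  set.seed(65)
  X <- matrix(runif(12), 4, 3)
  W <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 3, 2))
  lat <- matrix(runif(8, 0.01, 0.99), 4, 2)
  cfg <- list(lambda = 0.3, beta = 0.5, p = 0.05)
  out <- autoencoder_loss(cfg, X, X, W, lat)
  expect_equal(unname(out$terms["reconstruction"]), 0)
  expect_equal(unname(out$terms["l2"]), sum(W[[1]]^2) + sum(W[[2]]^2),
               tolerance = 1e-12)
  pn <- colMeans(lat)
  want_sp <- sum(0.05 * log(0.05 / pn) + 0.95 * log(0.95 / (1 - pn)))
  expect_equal(unname(out$terms["sparsity"]), want_sp, tolerance = 1e-12)
  expect_equal(out$total, 0.3 * out$terms[["l2"]] + 0.5 * want_sp,
               tolerance = 1e-12)
  # mean activation at the target: sparsity penalty vanishes
  lat_p <- matrix(0.05, 4, 2)
  expect_equal(unname(autoencoder_loss(cfg, X, X, W, lat_p)$terms["sparsity"]),
               0, tolerance = 1e-12)
  expect_warning(autoencoder_loss(cfg, X, X, W, matrix(1, 4, 2)), "clamping")
  expect_error(autoencoder_loss(cfg, X, X[1:2, ], W, lat), "shape differs")
})

test_that("a zero learning rate leaves every parameter untouched", {
  coh <- small_cohort(n = 20, Fk = 10, seed = 71)
  batch <- pad_in_sequence(coh)
  cfg <- tiny_net(lr = 0, epochs = 2)
  set.seed(5)
  mp <- longidistill:::build_model(10, 2, "cnnlstm", cfg)
  tr <- train_network(mp, batch, scheme = "none", config = cfg, seed = 9)
  expect_identical(tr$params$cell$W_f, mp$cell$W_f)
  expect_identical(tr$params$head$W2, mp$head$W2)
  expect_identical(tr$params$conv[[1]]$w, mp$conv[[1]]$w)
})

test_that("training reduces the loss and records a tidy trace", {
  coh <- small_cohort(n = 40, Fk = 12, seed = 72, effect_size = 1)
  batch <- pad_in_sequence(coh)
  fit <- ld_fit(batch, model = "cnnlstm", distill = "fd",
                config = tiny_net(epochs = 15, lr = 5e-3), seed = 2)
  tot <- fit$trace[fit$trace$split == "train" & fit$trace$term == "total", ]
  expect_equal(nrow(tot), 15L)
  expect_lt(tot$value[15], tot$value[1])
  expect_setequal(unique(fit$trace$term),
                  c("main_ce", "branch_ce", "branch_kl", "feature_l2", "total"))
  # the FD total recomposes from its logged terms at every epoch
  tr <- fit$trace[fit$trace$split == "train", ]
  for (ep in c(1, 8, 15)) {
    at <- function(term) tr$value[tr$epoch == ep & tr$term == term]
    expect_equal(at("total"),
                 at("main_ce") + at("branch_ce") + at("branch_kl") +
                   at("feature_l2"),
                 tolerance = 1e-9)
  }
})

test_that("sd training ramps alpha and keeps a teacher cache", {
  coh <- small_cohort(n = 20, Fk = 8, seed = 73)
  batch <- pad_in_sequence(coh)
  cfg <- tiny_net(epochs = 4, alpha_T = 0.8)
  set.seed(3)
  mp <- longidistill:::build_model(8, 2, "lstm", cfg)
  tr <- train_network(mp, batch, scheme = "sd", config = cfg, seed = 4)
  expect_equal(dim(tr$teacher), c(20L, 2L))
  expect_true(all(tr$teacher > 0 & tr$teacher < 1))
  terms <- unique(tr$trace$term[tr$trace$split == "train"])
  expect_setequal(terms, c("total", "hard_ce", "soft_ce"))
})

test_that("scheme guards and the non-finite abort fire", {
  coh <- small_cohort(n = 10, Fk = 6, seed = 74)
  batch <- pad_in_sequence(coh)
  cfg <- tiny_net(epochs = 1)
  set.seed(1)
  mp <- longidistill:::build_model(6, 2, "lstm", cfg)  # no branches
  expect_error(train_network(mp, batch, scheme = "fd", config = cfg),
               "requires branch classifiers")
  bad <- batch
  bad$values[1, 1, 1] <- NaN
  expect_error(train_network(mp, bad, scheme = "none", config = cfg),
               "non-finite loss")
  expect_error(ld_fit(batch, model = "ulstm", distill = "sd",
                      config = cfg),
               "does not support distillation")
})

test_that("the fitted-model object supports the classic verbs", {
  coh <- small_cohort(n = 24, Fk = 10, seed = 75)
  batch <- pad_in_sequence(coh)
  fit <- ld_fit(batch, model = "lstm", config = tiny_net(epochs = 3), seed = 6)
  expect_s3_class(fit, "ld_model")
  expect_output(print(fit), "ld_model: LSTM")
  expect_output(summary(fit), "train loss")
  P <- predict(fit, batch)
  expect_equal(dim(P), c(24L, 2L))
  expect_equal(colnames(P), fit$label_levels)
  expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  cl <- predict(fit, batch, type = "class")
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), fit$label_levels)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
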