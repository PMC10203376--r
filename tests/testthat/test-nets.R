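# Network primitives: LSTM/RNN cells, 1-D convolution, hybrid forward,
# masking semantics, sparse autoencoder.

zero_lstm <- function(D, H) {
  p <- lstm_parameters(D, H)
  for (nm in names(p)) p[[nm]][] <- 0
  p
}

test_that("all-zero LSTM weights give the closed-form first step", {
  p <- zero_lstm(3, 4)
  x <- c(0.2, 0.3, 0.5)
  st_tanh <- lstm_step(p, x)
  # gates 0.5, candidate tanh(0)=0 -> c=0; tanh squashing: h = 0.5*tanh(0)=0
  expect_equal(unname(st_tanh$c[1, ]), rep(0, 4))
  expect_equal(unname(st_tanh$h[1, ]), rep(0, 4))
  expect_equal(unname(st_tanh$gates$f[1, ]), rep(0.5, 4))
  expect_equal(unname(st_tanh$gates$i[1, ]), rep(0.5, 4))
  expect_equal(unname(st_tanh$gates$o[1, ]), rep(0.5, 4))
  # sigmoid squashing: h = 0.5 * sigmoid(0) = 0.25 exactly
  st_sig <- lstm_step(p, x, cell_activation = "sigmoid")
  expect_equal(unname(st_sig$h[1, ]), rep(0.25, 4))
})

test_that("a saturated forget gate carries the cell state unchanged", {
  p <- zero_lstm(2, 3)
  p$b_f[] <- 50    # f -> 1
  p$b_i[] <- -50   # i -> 0
  c0 <- c(0.7, -0.4, 1.2)
  st <- lstm_step(p, c(0, 0), state = list(h = rep(0, 3), c = c0, t = 0L))
  expect_equal(unname(st$c[1, ]), c0, tolerance = 1e-12)
})

test_that("lstm_step matches the scalar gate-by-gate oracle", {
  set.seed(101)
  for (act in c("tanh", "sigmoid")) {
    p <- lstm_parameters(5, 4)
    x <- rnorm(5); h0 <- rnorm(4) * 0.3; c0 <- rnorm(4) * 0.3
    st <- lstm_step(p, x, state = list(h = h0, c = c0, t = 3L),
                    cell_activation = act)
    or <- oracle_lstm_step(p, x, h0, c0, cell_activation = act)
    expect_lt(max(abs(st$h[1, ] - or$h)), 1e-10)
    expect_lt(max(abs(st$c[1, ] - or$c)), 1e-10)
    expect_equal(st$t, 4L)
  }
  expect_error(lstm_step(lstm_parameters(5, 4), rnorm(3)),
               "does not match cell input size")
})

test_that("lstm_step is batch-consistent row by row", {
  set.seed(7)
  p <- lstm_parameters(4, 3)
  X <- matrix(rnorm(8), 2, 4)
  bat <- lstm_step(p, X)
  for (r in 1:2)
    expect_equal(bat$h[r, ], lstm_step(p, X[r, ])$h[1, ], tolerance = 1e-12)
})

test_that("plain recurrent step has its closed forms and oracle", {
  p <- rnn_parameters(3, 2)
  p$W_x[] <- 0; p$W_h[] <- 0; p$b_l[] <- 0.5
  h <- rnn_step(p, c(1, 2, 3))
  expect_equal(unname(h[1, ]), rep(tanh(0.5), 2), tolerance = 1e-12)
  set.seed(11)
  p2 <- rnn_parameters(4, 3)
  x <- rnorm(4); h0 <- rnorm(3) * 0.2
  got <- rnn_step(p2, x, h_prev = h0)
  want <- tanh(as.vector(p2$W_x %*% x + p2$W_h %*% h0 + p2$b_l))
  expect_equal(unname(got[1, ]), want, tolerance = 1e-12)
  expect_true(all(abs(got) < 1))
})

test_that("convolution reproduces the worked examples", {
  p <- conv_parameters(1, 1, 3, stride = 1)
  p$w[] <- 1; p$b[] <- 0
  expect_equal(unname(conv_extract(p, c(1, 2, 3, 4))[1, ]), c(6, 9))
  # stride 2 keeps only the first window
  p2 <- conv_parameters(1, 1, 3, stride = 2)
  p2$w[] <- 1; p2$b[] <- 0
  expect_equal(unname(conv_extract(p2, c(1, 2, 3, 4))[1, ]), 6)
  # kernel size 1, weight 1 is the identity
  p3 <- conv_parameters(1, 1, 1)
  p3$w[] <- 1; p3$b[] <- 0
  expect_equal(unname(conv_extract(p3, c(0.4, 0.1, 0.5))[1, ]),
               c(0.4, 0.1, 0.5))
})

test_that("conv_extract matches the explicit double-loop oracle", {
  set.seed(21)
  p <- conv_parameters(3, 4, 3, stride = 2)
  x <- matrix(rnorm(3 * 11), 3, 11)
  expect_lt(max(abs(conv_extract(p, x) - oracle_conv(p$w, p$b, x, 2))), 1e-12)
  expect_error(conv_extract(p, matrix(rnorm(22), 2, 11)),
               "channel count")
  expect_error(conv_extract(p, matrix(rnorm(6), 3, 2)), "shorter than kernel")
  expect_error(conv_parameters(1, 1, 0), ">= 1")
})

test_that("lstm_forward mask [1,0,0,1] equals the unpadded two-step run", {
  set.seed(31)
  p <- lstm_parameters(3, 5)
  x1 <- runif(3); x4 <- runif(3)
  Xpad <- array(0, c(1, 4, 3))
  Xpad[1, 1, ] <- x1; Xpad[1, 4, ] <- x4
  mask <- matrix(c(1, 0, 0, 1), 1)
  fw <- lstm_forward(p, Xpad, use_mask = TRUE, mask = mask)
  s1 <- lstm_step(p, x1)
  s2 <- lstm_step(p, x4, state = s1)
  expect_equal(fw$last_hidden[1, ], s2$h[1, ], tolerance = 1e-12)
  # and the carried state is frozen across masked slots
  expect_equal(fw$hidden[1, 2, ], fw$hidden[1, 1, ], tolerance = 1e-15)
  expect_equal(fw$hidden[1, 3, ], fw$hidden[1, 1, ], tolerance = 1e-15)
  expect_error(lstm_forward(p, Xpad, use_mask = TRUE,
                            mask = matrix(0, 1, 4)),
               "all-zero observation mask")
})

test_that("unmasked forward treats padded zeros as real inputs", {
  set.seed(32)
  p <- lstm_parameters(3, 4)
  Xpad <- array(runif(12), c(1, 4, 3))
  Xpad[1, 2:3, ] <- 0
  fw <- lstm_forward(p, Xpad, use_mask = FALSE)
  st <- NULL
  for (t in 1:4) st <- lstm_step(p, Xpad[1, t, ], state = st)
  expect_equal(fw$last_hidden[1, ], st$h[1, ], tolerance = 1e-12)
  # zero input still moves the state (gates have biases/recurrence)
  expect_false(isTRUE(all.equal(fw$hidden[1, 2, ], fw$hidden[1, 1, ])))
})

test_that("cnn_lstm_forward with an identity conv reduces to the LSTM", {
  set.seed(41)
  Fk <- 6
  conv <- list(conv_parameters(1, 1, 1))
  conv[[1]]$w[] <- 1; conv[[1]]$b[] <- 0
  attr(conv, "output_dim") <- Fk
  lstm <- lstm_parameters(Fk, 5)
  head <- longidistill:::head_parameters(5, 4, 2)
  X <- array(runif(2 * 3 * Fk), c(2, 3, Fk))  # nonnegative: ReLU transparent
  withconv <- cnn_lstm_forward(conv, lstm, head, X)
  without <- cnn_lstm_forward(NULL, lstm, head, X)
  expect_equal(withconv, without, tolerance = 1e-12)
  expect_equal(dim(withconv), c(2L, 2L))
  expect_true(all(abs(rowSums(withconv) - 1) < 1e-12))
  expect_true(all(withconv > 0 & withconv < 1))
})

test_that("cnn_lstm_forward is deterministic and multi-label is sigmoid", {
  set.seed(42)
  conv <- list(conv_parameters(1, 2, 3, stride = 2))
  L2 <- longidistill:::conv_out_length(8, 3, 2)
  attr(conv, "output_dim") <- 2 * L2
  lstm <- lstm_parameters(2 * L2, 4)
  head <- longidistill:::head_parameters(4, 4, 3)
  X <- array(runif(5 * 2 * 8), c(5, 2, 8))
  a <- cnn_lstm_forward(conv, lstm, head, X, multi_label = TRUE)
  b <- cnn_lstm_forward(conv, lstm, head, X, multi_label = TRUE)
  expect_identical(a, b)
  expect_true(all(a > 0 & a < 1))
  # multi-label rows are independent Bernoullis: no sum-to-one constraint
  expect_false(all(abs(rowSums(a) - 1) < 1e-6))
})

test_that("concat pooling has its closed forms and loop oracle", {
  h <- matrix(c(1, 3, 2, 0, -1, 5), 3, 2, byrow = TRUE)  # T=3 slots, H=2
  out <- concat_pool(h)
  expect_equal(unname(out[1, ]), c(mean(c(1, 2, -1)), mean(c(3, 0, 5)),
                                   2, 5, -1, 5))
  # a single observed slot: mean = max = last
  one <- concat_pool(array(c(0.3, 0.7), c(1, 1, 2)))
  expect_equal(unname(one[1, ]), c(0.3, 0.7, 0.3, 0.7, 0.3, 0.7))
  # masked pooling ignores mask-0 slots for mean and max
  hid <- array(0, c(1, 3, 2))
  hid[1, 1, ] <- c(1, 1); hid[1, 2, ] <- c(9, 9); hid[1, 3, ] <- c(1, 1)
  # carry semantics: slot values after last observation repeat the state
  msk <- matrix(c(1, 0, 1), 1)
  got <- concat_pool(hid, msk)
  expect_equal(unname(got[1, ]), c(1, 1, 1, 1, 1, 1))
  expect_error(concat_pool(hid, matrix(0, 1, 3)), "no observed step")
})

test_that("autoencoder contract: latent must be strictly smaller", {
  expect_error(ae_config(input_size = 8, latent_size = 8), "latent")
  expect_error(ae_config(input_size = 8, latent_size = 9), "latent")
  cfg <- ae_config(input_size = 8, latent_size = 3)
  expect_equal(cfg$latent_size, 3L)
})

test_that("a near-full autoencoder overfits a tiny dataset", {
  set.seed(51)
  X <- matrix(runif(12 * 6), 12, 6)
  X <- X / rowSums(X)
  cfg <- ae_config(input_size = 6, latent_size = 5, lambda = 0, beta = 0)
  ae <- train_autoencoder(X, cfg, epochs = 2000, lr = 5e-2, seed = 2)
  Xh <- longidistill:::ae_forward(ae$params, X)$X_hat
  expect_lt(mean((X - Xh)^2), 1e-3)
})

test_that("the sparsity penalty drives mean activations toward p", {
  set.seed(52)
  X <- matrix(runif(60 * 10), 60, 10); X <- X / rowSums(X)
  cfg <- ae_config(input_size = 10, latent_size = 4, lambda = 0,
                   beta = 3, p = 0.05)
  ae <- train_autoencoder(X, cfg, epochs = 600, lr = 2e-2, seed = 3)
  lat <- ae_encode(ae, X)
  expect_true(all(colMeans(lat) < 2 * 0.05))
  expect_equal(dim(lat), c(60L, 4L))
})
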