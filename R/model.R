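## Model assembly: optional convolutional feature extractor shared across
## time points, a recurrent cell (LSTM or plain RNN), an MLP classifier head,
## and optional shallow branch classifiers for distillation. Forward and
## backward passes are written out explicitly; gradients mirror the parameter
## structure so a single optimizer walk updates everything.

## ---- recurrent core ---------------------------------------------------------

lstm_concat_weights <- function(cell) {
  list(Wx = rbind(cell$W_f, cell$W_i, cell$W_o, cell$W_c),
       U = rbind(cell$U_f, cell$U_i, cell$U_o, cell$U_c),
       b = c(cell$b_f, cell$b_i, cell$b_o, cell$b_c))
}

# forward over a (n, T, D) feature array. At slots where use_mask is on and
# the mask is 0 the state is carried through unchanged, so the hidden state
# at the final slot equals the hidden state at each subject's last
# observation.
cell_forward_full <- function(cell, feat, mask, use_mask, cell_activation) {
  d <- dim(feat); n <- d[1]; Tn <- d[2]
  H <- attr(cell, "hidden_size")
  is_lstm <- inherits(cell, "lstm_parameters")
  h_arr <- array(0, c(n, Tn, H))
  if (is_lstm) {
    cw <- lstm_concat_weights(cell)
    c_arr <- array(0, c(n, Tn, H))
    f_arr <- i_arr <- o_arr <- g_arr <- cs_arr <- array(0, c(n, Tn, H))
  } else {
    ht_arr <- array(0, c(n, Tn, H))  # pre-blend tanh activations
  }
  h_prev <- matrix(0, n, H); c_prev <- matrix(0, n, H)
  for (t in seq_len(Tn)) {
    x_t <- matrix(feat[, t, ], n)
    m <- if (use_mask) mask[, t] else rep(1, n)
    if (is_lstm) {
      Z <- sweep(x_t %*% t(cw$Wx) + h_prev %*% t(cw$U), 2, cw$b, `+`)
      f <- sigmoid(Z[, seq_len(H), drop = FALSE])
      i <- sigmoid(Z[, H + seq_len(H), drop = FALSE])
      o <- sigmoid(Z[, 2 * H + seq_len(H), drop = FALSE])
      g <- tanh(Z[, 3 * H + seq_len(H), drop = FALSE])
      c_tilde <- f * c_prev + i * g
      cs <- if (cell_activation == "tanh") tanh(c_tilde) else sigmoid(c_tilde)
      h_tilde <- o * cs
      h_t <- m * h_tilde + (1 - m) * h_prev
      c_t <- m * c_tilde + (1 - m) * c_prev
      f_arr[, t, ] <- f; i_arr[, t, ] <- i; o_arr[, t, ] <- o
      g_arr[, t, ] <- g; cs_arr[, t, ] <- cs
      c_arr[, t, ] <- c_t
    } else {
      a <- sweep(x_t %*% t(cell$W_x) + h_prev %*% t(cell$W_h), 2, cell$b_l, `+`)
      h_tilde <- tanh(a)
      h_t <- m * h_tilde + (1 - m) * h_prev
      ht_arr[, t, ] <- h_tilde
      c_t <- c_prev
    }
    h_arr[, t, ] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  out <- list(h = h_arr, h_last = h_prev, H = H, is_lstm = is_lstm)
  if (is_lstm) {
    out$c <- c_arr; out$f <- f_arr; out$i <- i_arr; out$o <- o_arr
    out$g <- g_arr; out$cs <- cs_arr; out$cw <- cw
  } else {
    out$ht <- ht_arr
  }
  out
}

# backward through time. dH_ext: (n, T, H) external gradients into the
# blended hidden states. Returns cell gradients plus d feat (n, T, D).
cell_backward_full <- function(cell, fw, feat, mask, use_mask,
                               cell_activation, dH_ext) {
  d <- dim(feat); n <- d[1]; Tn <- d[2]; D <- d[3]
  H <- fw$H
  dFeat <- array(0, c(n, Tn, D))
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  if (fw$is_lstm) {
    cw <- fw$cw
    dWx <- matrix(0, 4 * H, D); dU <- matrix(0, 4 * H, H); db <- numeric(4 * H)
  } else {
    dWxr <- matrix(0, H, D); dWhr <- matrix(0, H, H); dbr <- numeric(H)
  }
  for (t in rev(seq_len(Tn))) {
    m <- if (use_mask) mask[, t] else rep(1, n)
    dh_tot <- dh_next + matrix(dH_ext[, t, ], n)
    h_prev <- if (t > 1) matrix(fw$h[, t - 1, ], n) else matrix(0, n, H)
    x_t <- matrix(feat[, t, ], n)
    if (fw$is_lstm) {
      c_prev <- if (t > 1) matrix(fw$c[, t - 1, ], n) else matrix(0, n, H)
      f <- matrix(fw$f[, t, ], n); i <- matrix(fw$i[, t, ], n)
      o <- matrix(fw$o[, t, ], n); g <- matrix(fw$g[, t, ], n)
      cs <- matrix(fw$cs[, t, ], n)
      dh_tilde <- m * dh_tot
      dh_carry <- (1 - m) * dh_tot
      dc_tilde <- m * dc_next
      dc_carry <- (1 - m) * dc_next
      do_ <- dh_tilde * cs
      dcs <- dh_tilde * o
      dact <- if (cell_activation == "tanh") (1 - cs^2) else cs * (1 - cs)
      dc_tilde <- dc_tilde + dcs * dact
      df <- dc_tilde * c_prev
      di <- dc_tilde * g
      dg <- dc_tilde * i
      dc_prev <- dc_tilde * f + dc_carry
      dZ <- cbind(df * f * (1 - f), di * i * (1 - i),
                  do_ * o * (1 - o), dg * (1 - g^2))
      dWx <- dWx + crossprod(dZ, x_t)
      dU <- dU + crossprod(dZ, h_prev)
      db <- db + colSums(dZ)
      dFeat[, t, ] <- dZ %*% cw$Wx
      dh_next <- dZ %*% cw$U + dh_carry
      dc_next <- dc_prev
    } else {
      ht <- matrix(fw$ht[, t, ], n)
      dh_tilde <- m * dh_tot
      da <- dh_tilde * (1 - ht^2)
      dWxr <- dWxr + crossprod(da, x_t)
      dWhr <- dWhr + crossprod(da, h_prev)
      dbr <- dbr + colSums(da)
      dFeat[, t, ] <- da %*% cell$W_x
      dh_next <- da %*% cell$W_h + (1 - m) * dh_tot
    }
  }
  if (fw$is_lstm) {
    g1 <- seq_len(H)
    grads <- list(W_f = dWx[g1, , drop = FALSE], W_i = dWx[H + g1, , drop = FALSE],
                  W_o = dWx[2 * H + g1, , drop = FALSE], W_c = dWx[3 * H + g1, , drop = FALSE],
                  U_f = dU[g1, , drop = FALSE], U_i = dU[H + g1, , drop = FALSE],
                  U_o = dU[2 * H + g1, , drop = FALSE], U_c = dU[3 * H + g1, , drop = FALSE],
                  b_f = db[g1], b_i = db[H + g1], b_o = db[2 * H + g1],
                  b_c = db[3 * H + g1])
  } else {
    grads <- list(W_x = dWxr, W_h = dWhr, b_l = dbr)
  }
  list(grads = grads, d_feat = dFeat)
}

#' Run an LSTM over a padded longitudinal batch
#'
#' When `use_mask = TRUE` the state update at unobserved (mask 0) slots is
#' skipped: the hidden and cell state carry through unchanged, so the final
#' hidden state equals the state at each subject's last observation. When
#' `use_mask = FALSE` the padded zero vectors are processed like ordinary
#' inputs and the final slot's hidden state is used (the pad-in-sequence
#' training convention).
#'
#' @param params [lstm_parameters()].
#' @param batch a `padded_batch`, or a numeric array (subjects x slots x
#'   features).
#' @param use_mask whether to skip state updates at padded slots.
#' @param mask optional mask matrix when `batch` is a bare array.
#' @param cell_activation passed to [lstm_step()].
#' @return list with `hidden` (subjects x slots x hidden) and `last_hidden`
#'   (subjects x hidden).
#' @export
lstm_forward <- function(params, batch, use_mask = FALSE, mask = NULL,
                         cell_activation = "tanh") {
  if (inherits(batch, "padded_batch")) {
    values <- batch$values; mask <- batch$mask
  } else {
    values <- batch
    if (is.null(mask)) mask <- matrix(1, dim(values)[1], dim(values)[2])
  }
  if (use_mask && any(rowSums(mask) == 0))
    stop("subject with an all-zero observation mask")
  fw <- cell_forward_full(params, values, mask, use_mask, cell_activation)
  list(hidden = fw$h, last_hidden = fw$h_last)
}

#' Pool a hidden-state sequence by mean, max and last state
#'
#' Concatenates the mean of the hidden states, their elementwise maximum and
#' the last hidden state, all computed over observed (mask 1) steps only.
#'
#' @param hidden array (subjects x slots x hidden) or a single matrix
#'   (slots x hidden).
#' @param mask observation matrix (subjects x slots); all-ones when omitted.
#' @return matrix (subjects x 3*hidden): `[mean, max, last]`.
#' @export
concat_pool <- function(hidden, mask = NULL) {
  if (length(dim(hidden)) == 2) hidden <- array(hidden, c(1, dim(hidden)))
  d <- dim(hidden); n <- d[1]; Tn <- d[2]; H <- d[3]
  if (is.null(mask)) mask <- matrix(1, n, Tn)
  if (any(rowSums(mask) == 0)) stop("subject with no observed step")
  pool <- pool_forward(hidden, mask)
  cbind(pool$mean, pool$max, pool$last)
}

# internal pooling with caches for backward
pool_forward <- function(hidden, mask) {
  d <- dim(hidden); n <- d[1]; Tn <- d[2]; H <- d[3]
  n_obs <- rowSums(mask)
  mean_h <- matrix(0, n, H); max_h <- matrix(-Inf, n, H)
  argmax <- matrix(1L, n, H)
  for (t in seq_len(Tn)) {
    h_t <- matrix(hidden[, t, ], n)
    m <- mask[, t]
    mean_h <- mean_h + (m / n_obs) * h_t
    cand <- ifelse(matrix(m == 1, n, H), h_t, -Inf)
    upd <- cand > max_h
    argmax[upd] <- t
    max_h[upd] <- cand[upd]
  }
  last <- matrix(hidden[, Tn, ], n)  # carry makes slot T the last observation
  list(mean = mean_h, max = max_h, last = last, argmax = argmax, n_obs = n_obs)
}

## ---- whole-model parameter container ---------------------------------------

default_conv_layers <- function() {
  list(list(out_channels = 32, kernel_size = 5, stride = 2),
       list(out_channels = 32, kernel_size = 5, stride = 2))
}

#' Default network configuration
#'
#' Architecture and optimization defaults: a single-layer recurrent cell of
#' 128 hidden units; for convolutional models two 1-D convolution layers of
#' 32 channels, kernel 5, stride 2 with ReLU; an MLP head with one hidden
#' layer of 64 tanh units; adaptive-moment gradient descent at learning rate
#' 1e-3 with batch size 64 and 100 epochs; branch-classifier weights
#' (w_ce, w_kl, w_feat) all 1; progressive soft-target ceiling alpha_T 0.8.
#' Any element can be overridden via `...`.
#'
#' @param ... named overrides.
#' @return a named list of configuration values.
#' @export
net_config <- function(...) {
  cfg <- list(
    hidden_size = 128,
    head_hidden = 64,
    conv_layers = default_conv_layers(),
    cell_activation = "tanh",
    concat_pool = FALSE,
    epochs = 100,
    batch_size = 64,
    lr = 1e-3,
    beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
    fd_weights = c(w_ce = 1, w_kl = 1, w_feat = 1),
    alpha_T = 0.8,
    class_balance = FALSE,
    ae_latent = 64, ae_lambda = 1e-4, ae_beta = 0.1, ae_p = 0.05,
    ae_epochs = 50, ae_lr = 1e-3
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# assemble all trainable parameters; RNG state must be seeded by the caller.
# Branch parameters are drawn from a separate derived stream so the body
# initialization is identical with and without branches.
build_model <- function(input_dim, n_out, model = c("lstm", "cnnlstm", "rnn"),
                        config = net_config(), multi_label = FALSE,
                        n_branches = 0, branch_seed = NULL) {
  model <- match.arg(model)
  use_conv <- model %in% c("cnnlstm", "rnn")
  conv <- NULL
  D <- input_dim
  if (use_conv) {
    conv <- conv_stack_new(input_dim, config$conv_layers)
    D <- attr(conv, "output_dim")
  }
  cell <- if (model == "rnn") rnn_parameters(D, config$hidden_size)
          else lstm_parameters(D, config$hidden_size)
  head_in <- if (isTRUE(config$concat_pool)) 3 * config$hidden_size
             else config$hidden_size
  head <- head_parameters(head_in, config$head_hidden, n_out)
  branches <- NULL
  if (n_branches > 0) {
    if (isTRUE(config$concat_pool))
      stop("branch classifiers are not combined with concat pooling")
    if (!is.null(branch_seed)) set.seed(branch_seed)
    branches <- list()
    # shallow branch: attached to the per-time-point features (after the
    # conv stack when present) at the last valid slot
    branches[[1]] <- branch_parameters(D, config$hidden_size,
                                       config$head_hidden, n_out)
    if (n_branches > 1)
      branches[[2]] <- branch_parameters(config$hidden_size,
                                         config$hidden_size,
                                         config$head_hidden, n_out)
  }
  structure(list(conv = conv, cell = cell, head = head, branches = branches,
                 meta = list(model = model, input_dim = input_dim,
                             cell_input_dim = D, n_out = n_out,
                             hidden_size = config$hidden_size,
                             multi_label = multi_label,
                             cell_activation = config$cell_activation,
                             concat_pool = isTRUE(config$concat_pool))),
            class = "ld_parameters")
}

# full forward pass; X (n, T, F) values, mask (n, T)
model_forward <- function(mp, X, mask, use_mask) {
  d <- dim(X); n <- d[1]; Tn <- d[2]; Fk <- d[3]
  meta <- mp$meta
  if (use_mask && any(rowSums(mask) == 0))
    stop("subject with an all-zero observation mask")
  conv_fw <- NULL
  if (!is.null(mp$conv)) {
    flat <- matrix(X, n * Tn, Fk)
    conv_fw <- conv_stack_forward(mp$conv, flat, Fk)
    D <- ncol(conv_fw$output)
    feat <- array(conv_fw$output, c(n, Tn, D))
  } else {
    feat <- X; D <- Fk
  }
  cfw <- cell_forward_full(mp$cell, feat, mask, use_mask, meta$cell_activation)
  pool <- NULL
  if (meta$concat_pool) {
    pm <- if (use_mask) mask else matrix(1, n, Tn)
    pool <- pool_forward(cfw$h, pm)
    U <- cbind(pool$mean, pool$max, pool$last)
  } else {
    U <- cfw$h_last
  }
  hfw <- head_forward(mp$head, U)
  probs <- output_probs(hfw$Z, meta$multi_label)
  branch_fw <- NULL; branch_in <- NULL; last_slot <- NULL
  if (!is.null(mp$branches)) {
    last_slot <- if (use_mask) apply(mask, 1, function(r) max(which(r == 1)))
                 else rep(Tn, n)
    B1 <- matrix(0, n, D)
    for (t in unique(last_slot))
      B1[last_slot == t, ] <- matrix(feat[last_slot == t, t, ],
                                     sum(last_slot == t))
    branch_in <- list(B1, cfw$h_last)
    branch_fw <- lapply(seq_along(mp$branches), function(bi)
      branch_forward(mp$branches[[bi]], branch_in[[bi]]))
  }
  list(probs = probs, Z = hfw$Z, head_fw = hfw, cell_fw = cfw,
       conv_fw = conv_fw, feat = feat, U = U, pool = pool,
       branch_fw = branch_fw, branch_in = branch_in, last_slot = last_slot,
       branch_probs = if (is.null(branch_fw)) NULL else
         lapply(branch_fw, function(b) output_probs(b$Z, meta$multi_label)))
}

# full backward pass given gradients w.r.t. the main and branch output
# pre-activations (logits). Returns a gradient tree mirroring the parameters.
model_backward <- function(mp, fw, X, mask, use_mask, dZ_main,
                           dZ_branches = NULL) {
  d <- dim(X); n <- d[1]; Tn <- d[2]; Fk <- d[3]
  H <- mp$meta$hidden_size
  hb <- head_backward(mp$head, fw$U, fw$head_fw, dZ_main)
  dU <- hb$d_input
  dH_ext <- array(0, c(n, Tn, H))
  if (mp$meta$concat_pool) {
    dmean <- dU[, seq_len(H), drop = FALSE]
    dmax <- dU[, H + seq_len(H), drop = FALSE]
    dlast <- dU[, 2 * H + seq_len(H), drop = FALSE]
    pm <- if (use_mask) mask else matrix(1, n, Tn)
    for (t in seq_len(Tn)) {
      w <- pm[, t] / fw$pool$n_obs
      dH_ext[, t, ] <- dH_ext[, t, ] + w * dmean +
        (fw$pool$argmax == t) * dmax
    }
    dH_ext[, Tn, ] <- dH_ext[, Tn, ] + dlast
  } else {
    dH_ext[, Tn, ] <- dH_ext[, Tn, ] + dU
  }
  branch_grads <- NULL
  dFeat_branch <- NULL
  if (!is.null(mp$branches) && !is.null(dZ_branches)) {
    branch_grads <- vector("list", length(mp$branches))
    D <- mp$meta$cell_input_dim
    dFeat_branch <- array(0, c(n, Tn, D))
    for (bi in seq_along(mp$branches)) {
      bb <- branch_backward(mp$branches[[bi]], fw$branch_in[[bi]],
                            fw$branch_fw[[bi]], dZ_branches[[bi]])
      branch_grads[[bi]] <- bb$grads
      if (bi == 1) {
        for (t in unique(fw$last_slot)) {
          idx <- which(fw$last_slot == t)
          dFeat_branch[idx, t, ] <- dFeat_branch[idx, t, ] +
            bb$d_input[idx, , drop = FALSE]
        }
      } else {
        dH_ext[, Tn, ] <- dH_ext[, Tn, ] + bb$d_input
      }
    }
  }
  cb <- cell_backward_full(mp$cell, fw$cell_fw, fw$feat, mask, use_mask,
                           mp$meta$cell_activation, dH_ext)
  dFeat <- cb$d_feat
  if (!is.null(dFeat_branch)) dFeat <- dFeat + dFeat_branch
  conv_grads <- NULL
  if (!is.null(mp$conv)) {
    D <- dim(dFeat)[3]
    dflat <- matrix(dFeat, n * Tn, D)
    cg <- conv_stack_backward(mp$conv, fw$conv_fw$caches, dflat)
    conv_grads <- cg$grads
  }
  list(conv = conv_grads, cell = cb$grads, head = hb$grads,
       branches = branch_grads)
}

#' Forward pass of the hybrid convolutional-recurrent classifier
#'
#' Applies the convolutional feature extractor (weights shared across time
#' points) to each time point, runs the LSTM over the extracted feature
#' sequence, and classifies from the last output through the MLP head.
#'
#' @param conv list of [conv_parameters()] layers (the stack), or `NULL` for
#'   a pure LSTM.
#' @param lstm [lstm_parameters()] sized to the conv output dimension.
#' @param head head parameter list as produced inside [ld_fit()]; see
#'   Details.
#' @param batch a `padded_batch` or value array.
#' @param use_mask skip padded slots in the recurrence.
#' @param multi_label sigmoid (TRUE) vs normalized-exponential (FALSE)
#'   output activation.
#' @param cell_activation cell-state squashing, `"tanh"` or `"sigmoid"`.
#' @return matrix of class scores (probabilities), one row per subject.
#' @export
cnn_lstm_forward <- function(conv, lstm, head, batch, use_mask = FALSE,
                             multi_label = FALSE, cell_activation = "tanh") {
  if (inherits(batch, "padded_batch")) {
    X <- batch$values; mask <- batch$mask
  } else {
    X <- batch; mask <- matrix(1, dim(X)[1], dim(X)[2])
  }
  mp <- structure(list(conv = conv, cell = lstm, head = head, branches = NULL,
                       meta = list(model = if (is.null(conv)) "lstm" else "cnnlstm",
                                   input_dim = dim(X)[3],
                                   cell_input_dim = attr(lstm, "input_size"),
                                   n_out = nrow(head$W2),
                                   hidden_size = attr(lstm, "hidden_size"),
                                   multi_label = multi_label,
                                   cell_activation = cell_activation,
                                   concat_pool = FALSE)),
                  class = "ld_parameters")
  model_forward(mp, X, mask, use_mask)$probs
}
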