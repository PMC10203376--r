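## Network primitives: LSTM and RNN cells, 1-D convolution over the feature
## axis, and multi-layer perceptron heads. All forward math is explicit base-R
## matrix algebra; batches are matrices with one subject per row.

sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nrow, ncol, fan_in = ncol) {
  r <- 1 / sqrt(max(fan_in, 1))
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

#' Construct LSTM cell parameters
#'
#' Holds the four gate blocks of a single-layer LSTM: input-transform
#' weights `W_f`, `W_i`, `W_o`, `W_c` (hidden x input), recurrent weights
#' `U_f`, `U_i`, `U_o`, `U_c` (hidden x hidden) and biases `b_f`, `b_i`,
#' `b_o`, `b_c`. Weights are drawn uniformly with fan-in scaling from the
#' current RNG stream.
#'
#' @param input_size dimension of the per-time-point feature vector.
#' @param hidden_size dimension of the hidden and cell states.
#' @return an object of class `lstm_parameters`.
#' @export
lstm_parameters <- function(input_size, hidden_size) {
  p <- list(
    W_f = init_mat(hidden_size, input_size),
    W_i = init_mat(hidden_size, input_size),
    W_o = init_mat(hidden_size, input_size),
    W_c = init_mat(hidden_size, input_size),
    U_f = init_mat(hidden_size, hidden_size),
    U_i = init_mat(hidden_size, hidden_size),
    U_o = init_mat(hidden_size, hidden_size),
    U_c = init_mat(hidden_size, hidden_size),
    b_f = numeric(hidden_size),
    b_i = numeric(hidden_size),
    b_o = numeric(hidden_size),
    b_c = numeric(hidden_size)
  )
  structure(p, class = "lstm_parameters",
            input_size = input_size, hidden_size = hidden_size)
}

#' One LSTM time step
#'
#' Computes the gated state update
#' \deqn{f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f)}
#' \deqn{i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i)}
#' \deqn{o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o)}
#' \deqn{c_t = f_t \circ c_{t-1} + i_t \circ \tanh(W_c x_t + U_c h_{t-1} + b_c)}
#' and the hidden state \eqn{h_t = o_t \circ \phi(c_t)} where the cell
#' output squashing \eqn{\phi} is `tanh` by default (the conventional LSTM).
#' `cell_activation = "sigmoid"` applies a logistic squashing to the cell
#' state instead; both variants are kept because the two conventions appear
#' in the literature and differ numerically.
#'
#' @param params [lstm_parameters()].
#' @param x_t input at time t: a vector, or a matrix with one row per
#'   subject.
#' @param state list with `h` and `c` (vectors or matrices matching `x_t`'s
#'   batch shape) and time index `t`; at t = 0 both are zero.
#' @param cell_activation `"tanh"` (default) or `"sigmoid"`.
#' @return the updated state: list(h, c, t, gates = list(f, i, o, g)).
#' @export
lstm_step <- function(params, x_t, state = NULL,
                      cell_activation = c("tanh", "sigmoid")) {
  cell_activation <- match.arg(cell_activation)
  H <- attr(params, "hidden_size")
  if (is.null(dim(x_t))) x_t <- matrix(x_t, nrow = 1)
  n <- nrow(x_t)
  if (ncol(x_t) != attr(params, "input_size"))
    stop(sprintf("input dimension %d does not match cell input size %d",
                 ncol(x_t), attr(params, "input_size")))
  if (is.null(state)) state <- list(h = matrix(0, n, H), c = matrix(0, n, H), t = 0L)
  h_prev <- state$h; c_prev <- state$c
  if (is.null(dim(h_prev))) h_prev <- matrix(h_prev, nrow = n, ncol = H, byrow = TRUE)
  if (is.null(dim(c_prev))) c_prev <- matrix(c_prev, nrow = n, ncol = H, byrow = TRUE)

  f <- sigmoid(sweep(x_t %*% t(params$W_f) + h_prev %*% t(params$U_f), 2, params$b_f, `+`))
  i <- sigmoid(sweep(x_t %*% t(params$W_i) + h_prev %*% t(params$U_i), 2, params$b_i, `+`))
  o <- sigmoid(sweep(x_t %*% t(params$W_o) + h_prev %*% t(params$U_o), 2, params$b_o, `+`))
  g <- tanh(sweep(x_t %*% t(params$W_c) + h_prev %*% t(params$U_c), 2, params$b_c, `+`))
  c_t <- f * c_prev + i * g
  cs <- if (cell_activation == "tanh") tanh(c_t) else sigmoid(c_t)
  h_t <- o * cs
  list(h = h_t, c = c_t, t = state$t + 1L, gates = list(f = f, i = i, o = o, g = g))
}

#' Construct plain recurrent (RNN) cell parameters
#'
#' The gate-free baseline cell: `W_x` (hidden x input), `W_h`
#' (hidden x hidden) and bias `b_l`, with a tanh squashing of the
#' pre-activation.
#'
#' @inheritParams lstm_parameters
#' @return an object of class `rnn_parameters`.
#' @export
rnn_parameters <- function(input_size, hidden_size) {
  structure(list(W_x = init_mat(hidden_size, input_size),
                 W_h = init_mat(hidden_size, hidden_size),
                 b_l = numeric(hidden_size)),
            class = "rnn_parameters",
            input_size = input_size, hidden_size = hidden_size)
}

#' One plain recurrent step
#'
#' \eqn{a_t = W_x x_t + W_h h_{t-1} + b_l}, \eqn{h_t = \tanh(a_t)}.
#'
#' @param params [rnn_parameters()].
#' @param x_t input vector or batch matrix.
#' @param h_prev previous hidden state (zero when omitted).
#' @return the hidden state matrix, entries in (-1, 1).
#' @export
rnn_step <- function(params, x_t, h_prev = NULL) {
  H <- attr(params, "hidden_size")
  if (is.null(dim(x_t))) x_t <- matrix(x_t, nrow = 1)
  if (ncol(x_t) != attr(params, "input_size"))
    stop("input dimension does not match cell input size")
  n <- nrow(x_t)
  if (is.null(h_prev)) h_prev <- matrix(0, n, H)
  if (is.null(dim(h_prev))) h_prev <- matrix(h_prev, nrow = n, ncol = H, byrow = TRUE)
  a <- sweep(x_t %*% t(params$W_x) + h_prev %*% t(params$W_h), 2, params$b_l, `+`)
  tanh(a)
}

#' Construct 1-D convolution parameters
#'
#' A valid (no input padding) cross-correlation over the feature axis of a
#' single time point: `w` has dimension out_channels x in_channels x
#' kernel_size and `b` is one bias per output channel.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel_size window length (>= 1).
#' @param stride window step (>= 1).
#' @return an object of class `conv_parameters`.
#' @export
conv_parameters <- function(in_channels, out_channels, kernel_size, stride = 1) {
  if (kernel_size < 1 || stride < 1) stop("kernel_size and stride must be >= 1")
  w <- array(stats::runif(out_channels * in_channels * kernel_size,
                          -1 / sqrt(in_channels * kernel_size),
                          1 / sqrt(in_channels * kernel_size)),
             dim = c(out_channels, in_channels, kernel_size))
  structure(list(w = w, b = numeric(out_channels), stride = stride),
            class = "conv_parameters")
}

conv_out_length <- function(L, k, stride) {
  if (L < k) stop(sprintf("input length %d shorter than kernel size %d", L, k))
  (L - k) %/% stride + 1L
}

# weight matrix for the column-segment formulation: rows ordered channel-major
# (channel 1 positions 1..k, channel 2 positions 1..k, ...)
conv_weight_matrix <- function(params) {
  d <- dim(params$w)  # out x in x k
  Wm <- matrix(0, d[2] * d[3], d[1])
  for (ci in seq_len(d[2])) {
    m <- matrix(params$w[, ci, ], nrow = d[1])  # out x k
    Wm[(ci - 1) * d[3] + seq_len(d[3]), ] <- t(m)
  }
  Wm
}

# column indices of the input segment feeding output position p
conv_seg_index <- function(p, k, stride, L, in_channels) {
  as.vector(outer(seq_len(k), (seq_len(in_channels) - 1L) * L,
                  function(j, off) off + (p - 1L) * stride + j))
}

#' Apply a 1-D convolution to one feature vector or channel matrix
#'
#' Valid cross-correlation: output position d of channel o is
#' \eqn{O_{o,d} = \sum_{c}\sum_{j} w_{o,c,j}\, x_{c,(d-1)s + j} + b_o}.
#'
#' @param params [conv_parameters()].
#' @param x numeric vector (single channel) or matrix with one row per input
#'   channel.
#' @return matrix of out_channels rows x output positions.
#' @export
conv_extract <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) != dim(params$w)[2])
    stop("channel count of input does not match kernel")
  L <- ncol(x)
  k <- dim(params$w)[3]
  Lout <- conv_out_length(L, k, params$stride)
  Cout <- dim(params$w)[1]
  out <- matrix(0, Cout, Lout)
  for (p in seq_len(Lout)) {
    cols <- (p - 1L) * params$stride + seq_len(k)
    seg <- x[, cols, drop = FALSE]
    for (o in seq_len(Cout))
      out[o, p] <- sum(params$w[o, , ] * seg) + params$b[o]
  }
  out
}

## ---- batched conv stack (internal fast path) --------------------------------
## Batch layout: one row per (subject, time) pair; columns channel-blocked,
## column (c-1)*L + pos. ReLU follows every layer.

conv_stack_new <- function(input_dim, layers) {
  stack <- list()
  Cin <- 1L; L <- input_dim
  for (li in seq_along(layers)) {
    spec <- layers[[li]]
    p <- conv_parameters(Cin, spec$out_channels, spec$kernel_size, spec$stride)
    stack[[li]] <- p
    L <- conv_out_length(L, spec$kernel_size, spec$stride)
    Cin <- spec$out_channels
  }
  attr(stack, "output_dim") <- Cin * L
  stack
}

conv_stack_forward <- function(stack, X, input_dim) {
  caches <- vector("list", length(stack))
  cur <- X; L <- input_dim; Cin <- 1L
  for (li in seq_along(stack)) {
    p <- stack[[li]]
    k <- dim(p$w)[3]; Cout <- dim(p$w)[1]
    Lout <- conv_out_length(L, k, p$stride)
    Wm <- conv_weight_matrix(p)
    out <- matrix(0, nrow(cur), Cout * Lout)
    segs <- vector("list", Lout)
    for (pp in seq_len(Lout)) {
      idx <- conv_seg_index(pp, k, p$stride, L, Cin)
      seg <- cur[, idx, drop = FALSE]
      segs[[pp]] <- idx
      op <- seg %*% Wm
      op <- sweep(op, 2, p$b, `+`)
      out[, (seq_len(Cout) - 1L) * Lout + pp] <- op
    }
    act <- pmax(out, 0)
    caches[[li]] <- list(input = cur, act = act, segs = segs, Wm = Wm,
                         L = L, Lout = Lout, Cin = Cin, Cout = Cout)
    cur <- act; L <- Lout; Cin <- Cout
  }
  list(output = cur, caches = caches)
}

conv_stack_backward <- function(stack, caches, d_out) {
  grads <- vector("list", length(stack))
  d_cur <- d_out
  for (li in rev(seq_along(stack))) {
    p <- stack[[li]]; cc <- caches[[li]]
    d_pre <- d_cur * (cc$act > 0)
    dWm <- matrix(0, nrow(cc$Wm), ncol(cc$Wm))
    db <- numeric(cc$Cout)
    d_in <- matrix(0, nrow(cc$input), ncol(cc$input))
    col_of <- (seq_len(cc$Cout) - 1L) * cc$Lout
    for (pp in seq_len(cc$Lout)) {
      d_op <- d_pre[, col_of + pp, drop = FALSE]
      idx <- cc$segs[[pp]]
      seg <- cc$input[, idx, drop = FALSE]
      dWm <- dWm + crossprod(seg, d_op)
      db <- db + colSums(d_op)
      d_in[, idx] <- d_in[, idx] + d_op %*% t(cc$Wm)
    }
    # fold dWm back to the out x in x k array layout
    dw <- array(0, dim = dim(p$w))
    k <- dim(p$w)[3]
    for (ci in seq_len(cc$Cin))
      dw[, ci, ] <- t(dWm[(ci - 1) * k + seq_len(k), , drop = FALSE])
    grads[[li]] <- list(w = dw, b = db)
    d_cur <- d_in
  }
  list(grads = grads, d_input = d_cur)
}

## ---- MLP head ---------------------------------------------------------------

head_parameters <- function(input_dim, hidden, n_out) {
  list(W1 = init_mat(hidden, input_dim),
       b1 = numeric(hidden),
       W2 = init_mat(n_out, hidden),
       b2 = numeric(n_out))
}

head_forward <- function(head, X) {
  A1 <- tanh(sweep(X %*% t(head$W1), 2, head$b1, `+`))
  Z <- sweep(A1 %*% t(head$W2), 2, head$b2, `+`)
  list(A1 = A1, Z = Z)
}

head_backward <- function(head, X, fw, dZ) {
  dA1 <- dZ %*% head$W2
  dW2 <- crossprod(dZ, fw$A1)
  db2 <- colSums(dZ)
  dP1 <- dA1 * (1 - fw$A1^2)
  dW1 <- crossprod(dP1, X)
  db1 <- colSums(dP1)
  dX <- dP1 %*% head$W1
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), d_input = dX)
}

## branch (shallow) classifier: projection -> penultimate -> output.
## The penultimate weight matrix Ws is shaped like the main head's W1 so the
## feature-matching penalty compares like with like.
branch_parameters <- function(input_dim, hidden, pen_hidden, n_out) {
  list(Wp = init_mat(hidden, input_dim),
       bp = numeric(hidden),
       Ws = init_mat(pen_hidden, hidden),
       bs = numeric(pen_hidden),
       Wo = init_mat(n_out, pen_hidden),
       bo = numeric(n_out))
}

branch_forward <- function(br, X) {
  P <- tanh(sweep(X %*% t(br$Wp), 2, br$bp, `+`))
  A <- tanh(sweep(P %*% t(br$Ws), 2, br$bs, `+`))
  Z <- sweep(A %*% t(br$Wo), 2, br$bo, `+`)
  list(P = P, A = A, Z = Z)
}

branch_backward <- function(br, X, fw, dZ) {
  dA <- dZ %*% br$Wo
  dWo <- crossprod(dZ, fw$A)
  dbo <- colSums(dZ)
  dPA <- dA * (1 - fw$A^2)
  dWs <- crossprod(dPA, fw$P)
  dbs <- colSums(dPA)
  dP <- dPA %*% br$Ws
  dPP <- dP * (1 - fw$P^2)
  dWp <- crossprod(dPP, X)
  dbp <- colSums(dPP)
  dX <- dPP %*% br$Wp
  list(grads = list(Wp = dWp, bp = dbp, Ws = dWs, bs = dbs, Wo = dWo, bo = dbo),
       d_input = dX)
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

output_probs <- function(Z, multi_label) {
  if (multi_label) sigmoid(Z) else softmax(Z)
}
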