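## Sparse autoencoder used by the U-LSTM baseline: per-time-point abundance
## vectors are compressed to a latent code by an unsupervised first stage,
## then the frozen codes feed the recurrent classifier.

#' Sparse autoencoder configuration
#'
#' @param input_size number of input features.
#' @param latent_size number of latent neurons (must be smaller than the
#'   input size).
#' @param lambda L2 weight-regularization coefficient.
#' @param beta sparsity-penalty coefficient.
#' @param p sparsity target: desired average activation of each latent
#'   neuron, in (0, 1).
#' @return a list of class `ae_config`.
#' @export
ae_config <- function(input_size, latent_size, lambda = 1e-4, beta = 0.1,
                      p = 0.05) {
  if (latent_size >= input_size)
    stop("latent size must be smaller than the input size")
  if (p <= 0 || p >= 1) stop("sparsity target p must lie in (0, 1)")
  if (lambda < 0 || beta < 0) stop("lambda and beta must be >= 0")
  structure(list(input_size = input_size, latent_size = latent_size,
                 lambda = lambda, beta = beta, p = p),
            class = "ae_config")
}

ae_init <- function(config) {
  list(W1 = init_mat(config$latent_size, config$input_size),
       b1 = numeric(config$latent_size),
       W2 = init_mat(config$input_size, config$latent_size),
       b2 = numeric(config$input_size))
}

ae_forward <- function(params, X) {
  A <- sigmoid(sweep(X %*% t(params$W1), 2, params$b1, `+`))
  X_hat <- sweep(A %*% t(params$W2), 2, params$b2, `+`)
  list(latent = A, X_hat = X_hat)
}

#' Train a sparse autoencoder
#'
#' Minimizes the reconstruction + L2 + sparsity objective of
#' [autoencoder_loss()] by full-batch adaptive-moment gradient descent. The
#' latent layer uses a logistic activation so that average activations are
#' interpretable as Bernoulli rates for the sparsity penalty; the
#' reconstruction layer is linear.
#'
#' @param X matrix of observed abundance vectors (samples x features).
#' @param config an [ae_config()].
#' @param epochs number of full-batch gradient steps.
#' @param lr learning rate.
#' @param seed RNG seed for weight initialization.
#' @return list with `params`, `config` and the per-epoch loss `trace`.
#' @export
train_autoencoder <- function(X, config, epochs = 200, lr = 1e-2, seed = 1L) {
  X <- as.matrix(X)
  set.seed(seed)
  params <- ae_init(config)
  acfg <- net_config()
  state <- adam_new_state(list(ae = params))
  trace <- numeric(epochs)
  m <- nrow(X)
  for (ep in seq_len(epochs)) {
    fw <- ae_forward(params, X)
    A <- fw$latent
    loss <- autoencoder_loss(config, X, fw$X_hat,
                             list(params$W1, params$W2), A)
    trace[ep] <- loss$total
    dXhat <- 2 * (fw$X_hat - X) / m
    dW2 <- crossprod(dXhat, A) + 2 * config$lambda * params$W2
    db2 <- colSums(dXhat)
    dA <- dXhat %*% params$W2
    pn <- pmin(pmax(colMeans(A), 1e-7), 1 - 1e-7)
    d_sparse <- config$beta * (-config$p / pn + (1 - config$p) / (1 - pn)) / m
    dA <- sweep(dA, 2, d_sparse, `+`)
    dZ1 <- dA * A * (1 - A)
    dW1 <- crossprod(dZ1, X) + 2 * config$lambda * params$W1
    db1 <- colSums(dZ1)
    grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    st <- adam_step(list(ae = params), list(ae = grads), state, acfg, lr)
    params <- st$mp$ae
    state <- st$state
  }
  list(params = params, config = config, trace = trace)
}

#' Encode abundance vectors into the learned latent space
#'
#' @param ae result of [train_autoencoder()].
#' @param X matrix of abundance vectors.
#' @return latent activation matrix (samples x latent neurons), entries in
#'   (0, 1).
#' @export
ae_encode <- function(ae, X) {
  ae_forward(ae$params, as.matrix(X))$latent
}

# replace observed rows of a batch by their latent codes; padded rows stay 0
ae_transform_batch <- function(ae, batch) {
  d <- dim(batch$values)
  N <- ae$config$latent_size
  flat <- matrix(batch$values, d[1] * d[2], d[3])
  obs <- which(batch$mask == 1, arr.ind = TRUE)
  rows <- obs[, 1] + (obs[, 2] - 1L) * d[1]
  out <- matrix(0, d[1] * d[2], N)
  out[rows, ] <- ae_encode(ae, flat[rows, , drop = FALSE])
  batch$values <- array(out, c(d[1], d[2], N))
  batch$feature_ids <- paste0("latent", seq_len(N))
  batch
}
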