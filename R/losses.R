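## Loss functions for the self-distillation training schemes. All operate on
## row-wise probability matrices (one row per sample) and return scalars.

LOSS_EPS <- 1e-7

as_prob_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

#' Cross-entropy loss
#'
#' \eqn{-\frac{1}{m}\sum_i \sum_c y_{ic} \log \hat y_{ic}}: summed over
#' classes, averaged over samples. Targets may be one-hot or soft (as used
#' by the progressive self-distillation teacher). Predictions are clamped to
#' \[eps, 1 - eps\] before the logarithm.
#'
#' @param y target matrix (samples x classes), rows one-hot or soft.
#' @param y_hat predicted probability matrix of the same shape.
#' @param eps clamping constant.
#' @param sample_weights optional per-sample weights (e.g. inverse class
#'   frequencies); averaged with these weights when given.
#' @return scalar loss.
#' @export
cross_entropy <- function(y, y_hat, eps = LOSS_EPS, sample_weights = NULL) {
  y <- as_prob_matrix(y); y_hat <- as_prob_matrix(y_hat)
  if (!all(dim(y) == dim(y_hat))) stop("y and y_hat shapes differ")
  m <- nrow(y)
  if (m == 0) stop("cross_entropy of an empty batch")
  yh <- pmin(pmax(y_hat, eps), 1 - eps)
  per_sample <- -rowSums(y * log(yh))
  if (is.null(sample_weights)) mean(per_sample)
  else sum(sample_weights * per_sample) / m
}

#' Kullback-Leibler divergence between predicted distributions
#'
#' \eqn{\frac{1}{m}\sum_i \sum_c p_{ic} \log(p_{ic}/q_{ic})} in the standard
#' non-negative form, averaged over samples. Both arguments are clamped to
#' \[eps, 1 - eps\] and renormalized row-wise. In the distillation loss `p`
#' is the shallow (student) classifier and `q` the gradient-detached main
#' (teacher) classifier.
#'
#' @param p,q probability matrices (samples x classes), rows summing to 1.
#' @param eps clamping constant.
#' @return scalar divergence (>= 0 up to clamping error).
#' @export
kl_divergence <- function(p, q, eps = LOSS_EPS) {
  p <- as_prob_matrix(p); q <- as_prob_matrix(q)
  if (!all(dim(p) == dim(q))) stop("p and q shapes differ")
  p <- pmin(pmax(p, eps), 1 - eps); p <- p / rowSums(p)
  q <- pmin(pmax(q, eps), 1 - eps); q <- q / rowSums(q)
  mean(rowSums(p * log(p / q)))
}

#' Penultimate-feature matching penalty
#'
#' Mean squared elementwise difference between the weights of the layer
#' feeding the main classifier's output and the correspondingly shaped layer
#' of a shallow branch classifier.
#'
#' @param W_M,W_S weight matrices of identical shape.
#' @return scalar penalty.
#' @export
feature_l2 <- function(W_M, W_S) {
  if (!all(dim(as.matrix(W_M)) == dim(as.matrix(W_S))))
    stop("penultimate weight shapes differ between main and branch")
  mean((W_M - W_S)^2)
}

#' Branch-classifier distillation loss
#'
#' Total loss of the first self-distillation scheme: the main classifier's
#' cross-entropy plus, for every shallow branch, a weighted sum of (i) the
#' branch's own hard-label cross-entropy, (ii) the KL divergence from the
#' branch's distribution to the (detached) main classifier's distribution
#' and (iii) the penultimate-weight matching penalty.
#'
#' @param main_probs main classifier probability matrix.
#' @param branch_probs list of branch probability matrices.
#' @param y one-hot target matrix.
#' @param weights numeric vector `c(w_ce, w_kl, w_feat)`.
#' @param W_M main penultimate weight matrix.
#' @param W_S_list list of branch penultimate weight matrices.
#' @return list with `total` and a named `terms` vector.
#' @export
first_distillation_loss <- function(main_probs, branch_probs, y,
                                    weights = c(1, 1, 1),
                                    W_M = NULL, W_S_list = NULL) {
  if (length(branch_probs) < 1) stop("at least one branch is required")
  main_ce <- cross_entropy(y, main_probs)
  ce <- kl <- fl <- 0
  for (bi in seq_along(branch_probs)) {
    ce <- ce + cross_entropy(y, branch_probs[[bi]])
    kl <- kl + kl_divergence(branch_probs[[bi]], main_probs)
    if (!is.null(W_M) && !is.null(W_S_list))
      fl <- fl + feature_l2(W_M, W_S_list[[bi]])
  }
  total <- main_ce + weights[1] * ce + weights[2] * kl + weights[3] * fl
  list(total = total,
       terms = c(main_ce = main_ce, branch_ce = ce, branch_kl = kl,
                 feature_l2 = fl))
}

#' Linear soft-target weight schedule
#'
#' The progressive scheme ramps the soft-target weight linearly over
#' training: \eqn{\alpha_t = \alpha_T \cdot t / T}, starting near zero while
#' the model's own predictions are still uninformative and reaching
#' \eqn{\alpha_T} at the final epoch.
#'
#' @param alpha_T final soft-target weight in \[0, 1\].
#' @param T_total total number of training epochs.
#' @return an object of class `distill_schedule`.
#' @export
distill_schedule <- function(alpha_T = 0.8, T_total = 100) {
  if (alpha_T < 0 || alpha_T > 1) stop("alpha_T must lie in [0, 1]")
  if (T_total < 1) stop("T_total must be >= 1")
  structure(list(alpha_T = alpha_T, T_total = T_total),
            class = "distill_schedule")
}

#' @rdname distill_schedule
#' @param schedule a `distill_schedule`.
#' @param t current epoch in \[0, T\].
#' @export
alpha_at <- function(schedule, t) {
  if (any(t < 0 | t > schedule$T_total))
    stop("epoch t outside [0, T]")
  schedule$alpha_T * t / schedule$T_total
}

#' Progressive self-distillation loss
#'
#' The convex combination
#' \eqn{(1-\alpha_t)\,\mathrm{CE}(y, \hat y^{(t)}) +
#'      \alpha_t\,\mathrm{CE}(\hat y^{(t-1)}, \hat y^{(t)})}
#' where the teacher targets \eqn{\hat y^{(t-1)}} are the model's own
#' previous-epoch predictions, treated as fixed soft labels.
#'
#' @param y one-hot target matrix.
#' @param y_hat current predicted probabilities.
#' @param teacher previous-epoch probabilities for the same samples.
#' @param alpha_t current soft-target weight.
#' @return scalar loss.
#' @export
psk_loss <- function(y, y_hat, teacher, alpha_t) {
  if (is.null(teacher)) stop("teacher cache is empty")
  y <- as_prob_matrix(y); y_hat <- as_prob_matrix(y_hat)
  teacher <- as_prob_matrix(teacher)
  if (nrow(teacher) != nrow(y_hat))
    stop("teacher cache does not cover every sample in the batch")
  (1 - alpha_t) * cross_entropy(y, y_hat) +
    alpha_t * cross_entropy(teacher, y_hat)
}

# binary cross-entropy over independent labels (multi-label outcome mode);
# same conventions: sum over labels, mean over samples
binary_cross_entropy <- function(y, y_hat, eps = LOSS_EPS,
                                 sample_weights = NULL) {
  y <- as_prob_matrix(y); y_hat <- as_prob_matrix(y_hat)
  yh <- pmin(pmax(y_hat, eps), 1 - eps)
  per_sample <- -rowSums(y * log(yh) + (1 - y) * log(1 - yh))
  if (is.null(sample_weights)) mean(per_sample)
  else sum(sample_weights * per_sample) / nrow(y)
}

# Bernoulli KL per label for multi-label distillation
bernoulli_kl <- function(p, q, eps = LOSS_EPS) {
  p <- pmin(pmax(p, eps), 1 - eps)
  q <- pmin(pmax(q, eps), 1 - eps)
  mean(rowSums(p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))))
}

#' Sparse-autoencoder training loss
#'
#' Mean squared reconstruction error plus an L2 weight penalty and a
#' Bernoulli-KL sparsity penalty on the average activation of each latent
#' neuron:
#' \deqn{\frac{1}{m}\sum_i \|X_i - \hat X_i\|^2 + \lambda \sum_l \|W_l\|^2 +
#'       \beta \sum_n \mathrm{KL}(p \,\|\, p'_n)}
#' where \eqn{p'_n} is the observed mean activation of latent neuron n over
#' the batch. Mean activations outside (0, 1) are clamped to
#' \[1e-7, 1 - 1e-7\] with a warning.
#'
#' @param config list with `lambda`, `beta` and sparsity target `p`.
#' @param X input batch (samples x features).
#' @param X_hat reconstruction of the same shape.
#' @param weight_list list of weight matrices entering the L2 penalty.
#' @param latent latent activation matrix (samples x latent neurons).
#' @return list with `total` and a `terms` vector (reconstruction, l2,
#'   sparsity).
#' @export
autoencoder_loss <- function(config, X, X_hat, weight_list, latent) {
  X <- as.matrix(X); X_hat <- as.matrix(X_hat)
  if (!all(dim(X) == dim(X_hat))) stop("reconstruction shape differs from input")
  recon <- mean(rowSums((X - X_hat)^2))
  l2 <- sum(vapply(weight_list, function(W) sum(W^2), numeric(1)))
  p <- config$p
  pn <- colMeans(as.matrix(latent))
  if (any(pn <= 0 | pn >= 1)) {
    warning("latent mean activations outside (0,1); clamping")
    pn <- pmin(pmax(pn, 1e-7), 1 - 1e-7)
  }
  sparsity <- sum(p * log(p / pn) + (1 - p) * log((1 - p) / (1 - pn)))
  total <- recon + config$lambda * l2 + config$beta * sparsity
  list(total = total,
       terms = c(reconstruction = recon, l2 = l2, sparsity = sparsity))
}
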