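## Mini-batch training engine. One optimizer (adaptive-moment gradient
## descent) drives three schemes: plain hard-target training, branch-
## classifier distillation (shallow heads pulled toward the main
## classifier), and progressive self-distillation (previous-epoch
## predictions as ramped soft targets).

## ---- optimizer --------------------------------------------------------------

adam_like <- function(x) {
  if (is.list(x)) lapply(x, adam_like)
  else list(m = array(0, dim = if (is.null(dim(x))) length(x) else dim(x)),
            v = array(0, dim = if (is.null(dim(x))) length(x) else dim(x)))
}

adam_new_state <- function(grads) list(t = 0L, mv = adam_like(grads))

adam_walk <- function(par, grad, mv, lr, cfg, corr1, corr2) {
  if (is.list(grad)) {
    for (nm in seq_along(grad)) {
      if (is.null(grad[[nm]])) next
      key <- if (!is.null(names(grad)) && names(grad)[nm] != "") names(grad)[nm] else nm
      res <- adam_walk(par[[key]], grad[[nm]], mv[[key]], lr, cfg, corr1, corr2)
      par[[key]] <- res$par
      mv[[key]] <- res$mv
    }
    return(list(par = par, mv = mv))
  }
  m <- cfg$beta1 * mv$m + (1 - cfg$beta1) * grad
  v <- cfg$beta2 * mv$v + (1 - cfg$beta2) * grad^2
  upd <- lr * (m / corr1) / (sqrt(v / corr2) + cfg$adam_eps)
  list(par = par - upd, mv = list(m = m, v = v))
}

# one optimizer step; block_scale / trainable are named over the top-level
# parameter groups (conv, cell, head, branches)
adam_step <- function(mp, grads, state, cfg, lr,
                      block_scale = NULL, trainable = NULL) {
  state$t <- state$t + 1L
  corr1 <- 1 - cfg$beta1^state$t
  corr2 <- 1 - cfg$beta2^state$t
  for (blk in names(grads)) {
    if (is.null(grads[[blk]])) next
    if (!is.null(trainable) && !isTRUE(trainable[[blk]])) next
    scale <- if (is.null(block_scale) || is.null(block_scale[[blk]])) 1
             else block_scale[[blk]]
    res <- adam_walk(mp[[blk]], grads[[blk]], state$mv[[blk]],
                     lr * scale, cfg, corr1, corr2)
    mp[[blk]] <- res$par
    state$mv[[blk]] <- res$mv
  }
  list(mp = mp, state = state)
}

## ---- targets and loss gradients ---------------------------------------------

label_targets <- function(labels, label_levels, multi_label) {
  if (multi_label) {
    Y <- as.matrix(labels)
  } else {
    Y <- matrix(0, length(labels), length(label_levels))
    Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  }
  Y
}

class_sample_weights <- function(Y) {
  # inverse-frequency weights from one-hot rows, normalized to mean 1
  freq <- colMeans(Y)
  w <- 1 / pmax(freq[max.col(Y)], 1e-12)
  w / mean(w)
}

kl_grad_dZ <- function(B, Q, multi_label, m, eps = LOSS_EPS) {
  B <- pmin(pmax(B, eps), 1 - eps)
  Q <- pmin(pmax(Q, eps), 1 - eps)
  if (multi_label) {
    dfdb <- (log(B / Q) - log((1 - B) / (1 - Q))) / m
    dfdb * B * (1 - B)
  } else {
    g <- log(B / Q) + 1
    (B * (g - rowSums(B * g))) / m
  }
}

## ---- training loop ----------------------------------------------------------

#' Train a network on a padded longitudinal batch
#'
#' Runs mini-batch gradient training for a fixed number of epochs under one
#' of three schemes: `"none"` (hard-target cross-entropy), `"fd"` (branch-
#' classifier distillation: each shallow branch is trained with the hard
#' labels, pulled toward the detached main classifier's distribution, and
#' penalized for penultimate-weight mismatch) or `"sd"` (progressive
#' self-distillation: the loss blends hard targets with the model's own
#' previous-epoch predictions, the blend weight ramping linearly to
#' `alpha_T`). Only the main classifier is used at prediction time; branches
#' are training-only scaffolding.
#'
#' @param mp model parameters from the internal builder (or an `ld_model`'s
#'   `$params`).
#' @param batch training `padded_batch`.
#' @param scheme `"none"`, `"fd"` or `"sd"`.
#' @param config [net_config()] list.
#' @param valid_batch optional held-out `padded_batch`; its plain
#'   cross-entropy is recorded per epoch and the best checkpoint kept.
#' @param use_mask whether the recurrence skips padded slots.
#' @param seed integer seed for the epoch shuffling stream.
#' @return list with `params` (final), `best_params`, `trace` (data.frame
#'   epoch/split/term/value) and `teacher` (last soft-target cache, scheme
#'   `"sd"` only).
#' @export
train_network <- function(mp, batch, scheme = c("none", "fd", "sd"),
                          config = net_config(), valid_batch = NULL,
                          use_mask = FALSE, seed = 1L,
                          block_scale = NULL, unfreeze = FALSE) {
  scheme <- match.arg(scheme)
  if (scheme == "fd" && is.null(mp$branches))
    stop("scheme 'fd' requires branch classifiers")
  multi_label <- mp$meta$multi_label
  X <- batch$values; mask <- batch$mask
  n <- dim(X)[1]
  Y <- label_targets(batch$labels, batch$label_levels, multi_label)
  sw <- if (isTRUE(config$class_balance) && !multi_label)
          class_sample_weights(Y) else NULL
  Yv <- if (!is.null(valid_batch))
          label_targets(valid_batch$labels, valid_batch$label_levels,
                        multi_label) else NULL
  ce_fun <- if (multi_label) binary_cross_entropy else cross_entropy
  sched <- if (scheme == "sd") distill_schedule(config$alpha_T, config$epochs)
           else NULL
  teacher <- NULL
  if (scheme == "sd")
    teacher <- model_forward(mp, X, mask, use_mask)$probs
  state <- adam_new_state(model_zero_grads(mp))
  trace <- list()
  best <- list(loss = Inf, params = mp)
  set.seed(seed)
  blocks_deep_first <- c("head", "branches", "cell", "conv")
  for (epoch in seq_len(config$epochs)) {
    trainable <- NULL
    if (isTRUE(unfreeze)) {
      present <- blocks_deep_first[!vapply(mp[blocks_deep_first], is.null,
                                           logical(1))]
      open <- present[seq_len(min(epoch, length(present)))]
      trainable <- stats::setNames(as.list(names(mp) %in% open), names(mp))
    }
    ord <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    ep_terms <- NULL
    alpha <- if (scheme == "sd") alpha_at(sched, epoch) else 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
      Xb <- X[idx, , , drop = FALSE]
      Mb <- mask[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      m <- length(idx)
      fw <- model_forward(mp, Xb, Mb, use_mask)
      P <- fw$probs
      swb <- if (is.null(sw)) NULL else sw[idx]
      dZ <- (P - Yb) / m
      if (!is.null(swb)) dZ <- swb * dZ
      loss_terms <- c(main_ce = ce_fun(Yb, P, sample_weights = swb))
      dZ_branches <- NULL
      feat_grads <- NULL
      if (scheme == "sd") {
        Tb <- teacher[idx, , drop = FALSE]
        dZ <- ((1 - alpha) * (P - Yb) + alpha * (P - Tb)) / m
        loss_terms <- c(total = (1 - alpha) * ce_fun(Yb, P) +
                                alpha * ce_fun(Tb, P),
                        hard_ce = ce_fun(Yb, P), soft_ce = ce_fun(Tb, P))
      } else if (scheme == "fd") {
        w <- unname(config$fd_weights)
        dZ_branches <- vector("list", length(mp$branches))
        bce <- bkl <- bfl <- 0
        for (bi in seq_along(mp$branches)) {
          B <- fw$branch_probs[[bi]]
          dZ_b <- matrix(0, m, ncol(B))
          if (w[1] != 0) {
            dZ_b <- dZ_b + w[1] * (B - Yb) / m
            bce <- bce + ce_fun(Yb, B)
          }
          if (w[2] != 0) {
            dZ_b <- dZ_b + w[2] * kl_grad_dZ(B, P, multi_label, m)
            bkl <- bkl + (if (multi_label) bernoulli_kl(B, P)
                          else kl_divergence(B, P))
          }
          dZ_branches[[bi]] <- dZ_b
          if (w[3] != 0)
            bfl <- bfl + feature_l2(mp$head$W1, mp$branches[[bi]]$Ws)
        }
        loss_terms <- c(loss_terms, branch_ce = bce, branch_kl = bkl,
                        feature_l2 = bfl)
        loss_terms <- c(loss_terms,
                        total = unname(loss_terms["main_ce"]) +
                          w[1] * bce + w[2] * bkl + w[3] * bfl)
        if (w[3] != 0) {
          feat_grads <- list(dW1 = 0, dWs = vector("list", length(mp$branches)))
          for (bi in seq_along(mp$branches)) {
            diff <- 2 * (mp$head$W1 - mp$branches[[bi]]$Ws) /
              length(mp$head$W1)
            feat_grads$dW1 <- feat_grads$dW1 + w[3] * diff
            feat_grads$dWs[[bi]] <- -w[3] * diff
          }
        }
      }
      if (scheme == "none")
        loss_terms <- c(loss_terms, total = unname(loss_terms["main_ce"]))
      if (!all(is.finite(loss_terms)))
        stop(sprintf("non-finite loss at epoch %d (batch %d); aborting",
                     epoch, b))
      grads <- model_backward(mp, fw, Xb, Mb, use_mask, dZ, dZ_branches)
      if (!is.null(feat_grads)) {
        grads$head$W1 <- grads$head$W1 + feat_grads$dW1
        for (bi in seq_along(mp$branches))
          grads$branches[[bi]]$Ws <- grads$branches[[bi]]$Ws +
            feat_grads$dWs[[bi]]
      }
      st <- adam_step(mp, grads, state, config, config$lr,
                      block_scale = block_scale, trainable = trainable)
      mp <- st$mp; state <- st$state
      ep_terms <- if (is.null(ep_terms)) loss_terms * m
                  else ep_terms + loss_terms * m
    }
    ep_terms <- ep_terms / n
    for (term in names(ep_terms))
      trace[[length(trace) + 1]] <- data.frame(
        epoch = epoch, split = "train", term = term,
        value = unname(ep_terms[term]))
    if (scheme == "sd")
      teacher <- model_forward(mp, X, mask, use_mask)$probs
    if (!is.null(valid_batch)) {
      Pv <- model_forward(mp, valid_batch$values, valid_batch$mask,
                          use_mask)$probs
      vl <- ce_fun(Yv, Pv)
      trace[[length(trace) + 1]] <- data.frame(
        epoch = epoch, split = "valid", term = "main_ce", value = vl)
      if (vl < best$loss) best <- list(loss = vl, params = mp)
    }
  }
  list(params = mp,
       best_params = if (is.finite(best$loss)) best$params else mp,
       trace = do.call(rbind, trace),
       teacher = teacher)
}

# a zero-gradient tree matching the trainable parameters (optimizer shape)
model_zero_grads <- function(mp) {
  zero_of <- function(x) {
    if (is.list(x)) lapply(x, zero_of)
    else x * 0
  }
  g <- list(cell = zero_of(unclass_params(mp$cell)),
            head = zero_of(mp$head))
  if (!is.null(mp$conv))
    g$conv <- lapply(mp$conv, function(p) list(w = p$w * 0, b = p$b * 0))
  if (!is.null(mp$branches))
    g$branches <- lapply(mp$branches, zero_of)
  g
}

unclass_params <- function(p) {
  out <- unclass(p)
  attributes(out) <- list(names = names(out))
  out
}

model_predict_probs <- function(mp, batch, use_mask) {
  model_forward(mp, batch$values, batch$mask, use_mask)$probs
}
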