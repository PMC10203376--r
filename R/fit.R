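#' Fit a longitudinal microbiome outcome classifier
#'
#' The package's central fitting function. Builds and trains one of four
#' temporal architectures on a padded longitudinal batch:
#' \describe{
#'   \item{`"cnnlstm"`}{1-D convolutions over the taxon axis at each time
#'     point (weights shared across time) feeding an LSTM; the flagship
#'     model.}
#'   \item{`"lstm"`}{the LSTM alone on the raw abundance vectors.}
#'   \item{`"rnn"`}{the same pipeline with a plain tanh recurrent cell in
#'     place of the LSTM (baseline).}
#'   \item{`"ulstm"`}{a two-stage baseline: a sparse autoencoder is trained
#'     unsupervised on the observed abundance vectors, its encoder frozen,
#'     and the latent codes fed per time point into an LSTM classifier.}
#' }
#' Training optionally applies one of two self-knowledge distillation
#' schemes (`distill = "fd"` or `"sd"`, see [train_network()]); `"ulstm"`
#' supports hard-target training only.
#'
#' By convention, pad-in-sequence batches are trained without masking (the
#' recurrence sees the zero-padded slots and learns to refine them) while
#' pad-at-end batches are trained with the observation mask so the
#' recurrence skips the padded suffix; `use_mask` overrides this default.
#'
#' @param batch a `padded_batch` from [pad_in_sequence()] or [pad_at_end()].
#' @param model architecture, one of `"cnnlstm"`, `"lstm"`, `"rnn"`,
#'   `"ulstm"`.
#' @param distill `"none"`, `"fd"` (branch-classifier distillation) or
#'   `"sd"` (progressive self-distillation).
#' @param config a [net_config()] list.
#' @param valid_batch optional held-out batch for per-epoch validation loss
#'   and best-checkpoint selection.
#' @param use_mask logical; defaults from the batch's padding strategy.
#' @param seed integer seed controlling weight initialization and epoch
#'   shuffling.
#' @return an object of class `ld_model`.
#' @examples
#' syn <- generate(synth_config(n_subjects = 30, n_features = 20,
#'                              n_timepoints = 3, seed = 1))
#' coh <- assemble_cohort(syn$table, syn$meta, canonical_grid = 0:2)
#' fit <- ld_fit(pad_in_sequence(coh), model = "lstm",
#'               config = net_config(hidden_size = 8, head_hidden = 4,
#'                                   epochs = 3), seed = 1)
#' print(fit)
#' @export
ld_fit <- function(batch, model = c("cnnlstm", "lstm", "rnn", "ulstm"),
                   distill = c("none", "fd", "sd"), config = net_config(),
                   valid_batch = NULL,
                   use_mask = identical(batch$strategy_tag, "pad_at_end"),
                   seed = 1L) {
  model <- match.arg(model)
  distill <- match.arg(distill)
  stopifnot(inherits(batch, "padded_batch"))
  if (model == "ulstm" && distill != "none")
    stop("the autoencoder baseline does not support distillation schemes")
  n_out <- length(batch$label_levels)
  ae <- NULL
  if (model == "ulstm") {
    obs <- observed_rows(batch)
    ae <- train_autoencoder(obs,
                            ae_config(ncol(obs), config$ae_latent,
                                      lambda = config$ae_lambda,
                                      beta = config$ae_beta, p = config$ae_p),
                            epochs = config$ae_epochs, lr = config$ae_lr,
                            seed = seed)
    batch <- ae_transform_batch(ae, batch)
    if (!is.null(valid_batch)) valid_batch <- ae_transform_batch(ae, valid_batch)
  }
  input_dim <- dim(batch$values)[3]
  set.seed(seed)
  mp <- build_model(input_dim, n_out,
                    model = if (model %in% c("lstm", "ulstm")) "lstm"
                            else if (model == "rnn") "rnn" else "cnnlstm",
                    config = config, multi_label = batch$multi_label,
                    n_branches = if (distill == "fd") 2 else 0,
                    branch_seed = seed + 10007L)
  tr <- train_network(mp, batch, scheme = distill, config = config,
                      valid_batch = valid_batch, use_mask = use_mask,
                      seed = seed + 20011L)
  structure(list(params = tr$params, best_params = tr$best_params,
                 trace = tr$trace, model = model, distill = distill,
                 config = config, use_mask = use_mask, ae = ae,
                 label_levels = batch$label_levels,
                 multi_label = batch$multi_label,
                 strategy = batch$strategy_tag,
                 feature_ids = batch$feature_ids,
                 input_features = if (is.null(ae)) input_dim
                                  else ae$config$input_size,
                 seed = seed),
            class = "ld_model")
}

n_parameters <- function(x) {
  if (is.list(x)) sum(vapply(x, n_parameters, numeric(1)))
  else if (is.numeric(x)) length(x) else 0
}

#' @export
print.ld_model <- function(x, ...) {
  cat(sprintf("ld_model: %s (distill: %s, padding: %s%s)\n",
              toupper(x$model), x$distill, x$strategy,
              if (x$use_mask) ", masked" else ""))
  cat(sprintf("  %d input features -> %d outcome %s; %s trainable parameters\n",
              x$input_features, length(x$label_levels),
              if (x$multi_label) "labels" else "classes",
              format(n_parameters(x$params[c("conv", "cell", "head", "branches")]),
                     big.mark = ",")))
  fin <- x$trace[x$trace$split == "train" & x$trace$term == "total", ]
  if (nrow(fin) > 0)
    cat(sprintf("  final training loss: %.4f after %d epochs\n",
                fin$value[nrow(fin)], max(fin$epoch)))
  invisible(x)
}

#' @export
summary.ld_model <- function(object, ...) {
  print(object)
  tr <- object$trace
  for (sp in unique(tr$split)) {
    sub <- tr[tr$split == sp & tr$term %in% c("total", "main_ce"), ]
    sub <- sub[sub$term == sub$term[1], ]
    cat(sprintf("  %s loss: first %.4f, min %.4f (epoch %d), last %.4f\n",
                sp, sub$value[1], min(sub$value), sub$epoch[which.min(sub$value)],
                sub$value[nrow(sub)]))
  }
  invisible(object)
}

#' Predict outcome probabilities or classes
#'
#' @param object an `ld_model`.
#' @param newdata a `padded_batch` with the same feature space the model was
#'   trained on.
#' @param type `"prob"` for the probability matrix, `"class"` for hard
#'   labels (argmax in the mutually exclusive mode, 0.5-thresholded in the
#'   multi-label mode).
#' @param use_best use the best-validation checkpoint instead of the final
#'   weights.
#' @param ... unused.
#' @return probability matrix or label vector/matrix.
#' @export
predict.ld_model <- function(object, newdata, type = c("prob", "class"),
                             use_best = FALSE, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "padded_batch"))
  if (!is.null(object$ae)) newdata <- ae_transform_batch(object$ae, newdata)
  mp <- if (use_best) object$best_params else object$params
  P <- model_predict_probs(mp, newdata, object$use_mask)
  colnames(P) <- object$label_levels
  if (type == "prob") return(P)
  if (object$multi_label) (P >= 0.5) * 1
  else factor(object$label_levels[max.col(P)], levels = object$label_levels)
}

#' Plot the training loss trace
#'
#' @param x an `ld_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ld_model <- function(x, ...) {
  tr <- x$trace[x$trace$term %in% c("total", "main_ce"), ]
  splits <- split(tr, interaction(tr$split, tr$term, drop = TRUE))
  ep <- sort(unique(tr$epoch))
  ys <- vapply(splits, function(s) s$value[match(ep, s$epoch)],
               numeric(length(ep)))
  graphics::matplot(ep, ys, type = "l", lty = 1, xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", legend = names(splits), lty = 1,
                   col = seq_along(splits), bty = "n")
  invisible(x)
}
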