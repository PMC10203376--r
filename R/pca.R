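#' Fit a principal-component feature reduction
#'
#' Fits PCA on a matrix of observed per-sample abundance vectors (time slots
#' are treated as independent rows). To avoid information leakage the fit
#' must use training-fold rows only; [apply_pca()] then projects any batch
#' into the learned component space.
#'
#' @param train_values numeric matrix of observed rows (samples x features).
#' @param n_components number of components to retain (study default 300).
#' @return an object of class `pca_mapping` with the centering vector,
#'   rotation matrix and per-component explained variance.
#' @export
fit_pca <- function(train_values, n_components = 300) {
  train_values <- as.matrix(train_values)
  bound <- min(nrow(train_values), ncol(train_values))
  if (n_components > bound)
    stop(sprintf("n_components (%d) exceeds min(n_rows=%d, n_features=%d) = %d",
                 n_components, nrow(train_values), ncol(train_values), bound))
  pc <- stats::prcomp(train_values, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 sdev = pc$sdev[seq_len(n_components)],
                 n_components = n_components),
            class = "pca_mapping")
}

#' @export
print.pca_mapping <- function(x, ...) {
  cat(sprintf("pca_mapping: %d features -> %d components\n",
              nrow(x$rotation), x$n_components))
  invisible(x)
}

# project a plain matrix of observed rows
pca_project <- function(mapping, X) {
  sweep(as.matrix(X), 2, mapping$center) %*% mapping$rotation
}

#' Project a padded batch into PCA space
#'
#' Observed rows (mask 1) are centered and rotated; padded rows stay exactly
#' zero so the padding contract of the batch is preserved.
#'
#' @param mapping a [fit_pca()] result.
#' @param batch a `padded_batch`.
#' @return a `padded_batch` whose feature dimension is `n_components`.
#' @export
apply_pca <- function(mapping, batch) {
  stopifnot(inherits(mapping, "pca_mapping"), inherits(batch, "padded_batch"))
  d <- dim(batch$values)
  out <- array(0, dim = c(d[1], d[2], mapping$n_components))
  obs <- which(batch$mask == 1, arr.ind = TRUE)
  if (nrow(obs) > 0) {
    flat <- matrix(batch$values, d[1] * d[2], d[3])
    rows <- obs[, 1] + (obs[, 2] - 1L) * d[1]
    proj <- pca_project(mapping, flat[rows, , drop = FALSE])
    flat_out <- matrix(0, d[1] * d[2], mapping$n_components)
    flat_out[rows, ] <- proj
    out <- array(flat_out, dim = c(d[1], d[2], mapping$n_components))
  }
  batch$values <- out
  batch$feature_ids <- paste0("PC", seq_len(mapping$n_components))
  batch
}

# gather all observed rows of a batch into a samples x features matrix
observed_rows <- function(batch) {
  d <- dim(batch$values)
  flat <- matrix(batch$values, d[1] * d[2], d[3])
  obs <- which(batch$mask == 1, arr.ind = TRUE)
  flat[obs[, 1] + (obs[, 2] - 1L) * d[1], , drop = FALSE]
}
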