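#' Assemble per-subject longitudinal sequences
#'
#' Joins an abundance table with its sample metadata into a cohort of
#' per-subject time-ordered observation sequences on a fixed canonical time
#' grid. The grid (e.g. study weeks 0/4/12/52, or monthly indices) is
#' supplied explicitly rather than inferred, so that slot alignment is
#' deterministic across runs and studies.
#'
#' A subject's outcome is a subject-level property: samples of one subject
#' carrying different labels are an error, never silently resolved.
#'
#' @param table an [abundance_table()].
#' @param meta a [sample_metadata()] data.frame covering every sample.
#' @param canonical_grid strictly increasing numeric vector of valid time
#'   points.
#' @param multi_label logical; `TRUE` when the label columns are per-outcome
#'   binary indicators, `FALSE` for one mutually exclusive categorical label.
#' @return an object of class `longitudinal_cohort`: a list with `subjects`
#'   (each a list of `id`, `times`, `X` matrix of observations x features,
#'   and `label`), `canonical_grid`, `feature_ids`, `label_levels` and
#'   `multi_label`.
#' @export
assemble_cohort <- function(table, meta, canonical_grid,
                            multi_label = length(attr(meta, "label_cols")) > 1) {
  stopifnot(inherits(table, "abundance_table"))
  if (!inherits(meta, "sample_metadata")) meta <- sample_metadata(meta)
  canonical_grid <- as.numeric(canonical_grid)
  if (length(canonical_grid) == 0) stop("canonical_grid must be non-empty")
  if (is.unsorted(canonical_grid, strictly = TRUE))
    stop("canonical_grid must be strictly increasing")
  label_cols <- attr(meta, "label_cols")

  idx <- match(table$sample_ids, meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) without metadata: ",
         paste(utils::head(table$sample_ids[is.na(idx)], 3), collapse = ", "))
  meta <- meta[idx, , drop = FALSE]

  off <- which(!(meta$time_point %in% canonical_grid))
  if (length(off) > 0)
    stop(sprintf("time point off the canonical grid: sample '%s' at %s",
                 meta$sample_id[off[1]], meta$time_point[off[1]]))

  if (multi_label) {
    lab_mat <- as.matrix(meta[, label_cols, drop = FALSE])
    storage.mode(lab_mat) <- "double"
    if (any(!(lab_mat %in% c(0, 1))))
      stop("multi-label columns must be binary 0/1")
    label_levels <- label_cols
  } else {
    lab_vec <- as.character(meta[[label_cols[1]]])
    label_levels <- sort(unique(lab_vec))
  }

  subjects <- list()
  for (sid in unique(meta$subject_id)) {
    rows <- which(meta$subject_id == sid)
    if (length(rows) == 0) next
    ord <- rows[order(meta$time_point[rows])]
    if (multi_label) {
      labs <- lab_mat[ord, , drop = FALSE]
      if (nrow(unique(labs)) > 1)
        stop("conflicting labels across samples of subject ", sid)
      label <- labs[1, ]
    } else {
      labs <- unique(lab_vec[ord])
      if (length(labs) > 1)
        stop("conflicting labels across samples of subject ", sid, ": ",
             paste(labs, collapse = " vs "))
      label <- labs
    }
    subjects[[length(subjects) + 1L]] <- list(
      id = sid,
      times = meta$time_point[ord],
      X = table$values[ord, , drop = FALSE],
      label = label
    )
  }

  structure(list(subjects = subjects,
                 canonical_grid = canonical_grid,
                 feature_ids = table$feature_ids,
                 label_levels = label_levels,
                 multi_label = multi_label),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  n_obs <- vapply(x$subjects, function(s) length(s$times), integer(1))
  cat(sprintf("longitudinal_cohort: %d subjects, %d features, grid (%s)\n",
              length(x$subjects), length(x$feature_ids),
              paste(x$canonical_grid, collapse = ", ")))
  cat(sprintf("  observations per subject: %d-%d (median %g)\n",
              min(n_obs), max(n_obs), stats::median(n_obs)))
  cat(sprintf("  outcome mode: %s (%s)\n",
              if (x$multi_label) "multi-label" else "multi-class",
              paste(x$label_levels, collapse = ", ")))
  invisible(x)
}

cohort_labels <- function(cohort) {
  if (cohort$multi_label) {
    do.call(rbind, lapply(cohort$subjects, function(s) s$label))
  } else {
    factor(vapply(cohort$subjects, function(s) s$label, character(1)),
           levels = cohort$label_levels)
  }
}

new_padded_batch <- function(values, mask, labels, subject_ids, strategy,
                             grid, label_levels, multi_label,
                             feature_ids = NULL) {
  stopifnot(length(dim(values)) == 3, all(dim(values)[1:2] == dim(mask)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(dim(values)[3]))
  structure(list(values = values, mask = mask, labels = labels,
                 subject_ids = subject_ids, strategy_tag = strategy,
                 canonical_grid = grid, label_levels = label_levels,
                 multi_label = multi_label, feature_ids = feature_ids),
            class = "padded_batch")
}

#' Pad subjects in sequence on the canonical grid
#'
#' Places each observed sample at its canonical time slot and fills every
#' unobserved slot with a zero vector, preserving the temporal order and
#' spacing of the study grid. The accompanying mask marks observed slots
#' with 1 and zero-filled slots with 0.
#'
#' @param cohort a [assemble_cohort()] result.
#' @return a `padded_batch` with `values` (subjects x slots x features),
#'   `mask` (subjects x slots), `labels`, and `strategy_tag`
#'   `"pad_in_sequence"`.
#' @export
pad_in_sequence <- function(cohort) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  grid <- cohort$canonical_grid
  n <- length(cohort$subjects)
  Tn <- length(grid)
  Fk <- length(cohort$feature_ids)
  values <- array(0, dim = c(n, Tn, Fk))
  mask <- matrix(0, n, Tn)
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    slots <- match(s$times, grid)
    values[i, slots, ] <- s$X
    mask[i, slots] <- 1
  }
  new_padded_batch(values, mask, cohort_labels(cohort),
                   vapply(cohort$subjects, `[[`, character(1), "id"),
                   "pad_in_sequence", grid, cohort$label_levels,
                   cohort$multi_label, cohort$feature_ids)
}

#' Pad subjects at the end of the sequence
#'
#' Compacts each subject's observations to the leading slots in time order
#' and zero-fills the suffix; the mask is a prefix of ones. The number of
#' slots defaults to the maximum observation count in the cohort, or to the
#' full grid length with `use_grid_length = TRUE`.
#'
#' @param cohort a [assemble_cohort()] result.
#' @param use_grid_length logical; force `T_slots = length(canonical_grid)`.
#' @return a `padded_batch` with `strategy_tag` `"pad_at_end"`.
#' @export
pad_at_end <- function(cohort, use_grid_length = FALSE) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  grid <- cohort$canonical_grid
  n <- length(cohort$subjects)
  n_obs <- vapply(cohort$subjects, function(s) length(s$times), integer(1))
  Tn <- if (use_grid_length) length(grid) else max(n_obs)
  Fk <- length(cohort$feature_ids)
  values <- array(0, dim = c(n, Tn, Fk))
  mask <- matrix(0, n, Tn)
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    k <- length(s$times)
    values[i, seq_len(k), ] <- s$X
    mask[i, seq_len(k)] <- 1
  }
  new_padded_batch(values, mask, cohort_labels(cohort),
                   vapply(cohort$subjects, `[[`, character(1), "id"),
                   "pad_at_end", grid, cohort$label_levels,
                   cohort$multi_label, cohort$feature_ids)
}

#' @export
print.padded_batch <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("padded_batch [%s]: %d subjects x %d slots x %d features (%.0f%% observed)\n",
              x$strategy_tag, d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Subset a padded batch by subject index
#'
#' Keeps the selected subjects' values, mask, labels and identifiers
#' aligned; used to carve training/test batches out of a padded cohort.
#'
#' @param batch a `padded_batch`.
#' @param idx integer subject indices to keep.
#' @return a `padded_batch` over the selected subjects.
#' @export
subset_batch <- function(batch, idx) {
  labels <- if (batch$multi_label) batch$labels[idx, , drop = FALSE]
            else batch$labels[idx]
  new_padded_batch(batch$values[idx, , , drop = FALSE],
                   batch$mask[idx, , drop = FALSE],
                   labels, batch$subject_ids[idx], batch$strategy_tag,
                   batch$canonical_grid, batch$label_levels,
                   batch$multi_label, batch$feature_ids)
}

#' Truncate a cohort to its first observed time points
#'
#' Keeps each subject's first `horizon` observations (fewer when a subject
#' has fewer), dropping later samples. Used by the sensitivity analysis over
#' the amount of history available to the model.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param horizon positive integer number of leading observations to keep.
#' @return a truncated `longitudinal_cohort` on the same grid.
#' @export
truncate_history <- function(cohort, horizon) {
  if (horizon < 1) stop("horizon must be >= 1")
  out <- cohort
  out$subjects <- lapply(cohort$subjects, function(s) {
    k <- min(horizon, length(s$times))
    s$times <- s$times[seq_len(k)]
    s$X <- s$X[seq_len(k), , drop = FALSE]
    s
  })
  out
}
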