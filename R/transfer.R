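## Cross-study transfer: features of two studies are made comparable by
## aggregating abundances to a shared taxonomic rank and intersecting the
## group names, then a model trained on the source study is fine-tuned on
## the target with discriminative per-layer learning rates, gradual
## unfreezing and concat pooling.

#' Read a taxonomy map from TSV
#'
#' Expects two columns: `feature_id` and a semicolon-delimited lineage
#' (kingdom through genus). Greengenes-style rank prefixes (`k__`, `p__`,
#' ...) are tolerated and stripped.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `feature_id`, `kingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`.
#' @export
read_taxonomy_map <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (!all(c("feature_id", "lineage") %in% colnames(raw)))
    stop("taxonomy TSV must have columns feature_id and lineage")
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(raw$lineage, ";")
  lin <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[kpcofgs]__", "", p)
    length(p) <- 6
    p
  }, character(6)))
  out <- data.frame(feature_id = as.character(raw$feature_id), lin,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("feature_id", ranks)
  out
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Sums the relative abundances of all features sharing a group name at the
#' chosen rank; per-sample totals are conserved. Group columns are ordered
#' lexicographically so the aggregated feature space is deterministic.
#'
#' @param table an [abundance_table()].
#' @param tax taxonomy data.frame as from [read_taxonomy_map()].
#' @param rank one of kingdom, phylum, class, order, family, genus.
#' @return an `abundance_table` over rank groups.
#' @export
aggregate_to_rank <- function(table, tax, rank = "phylum") {
  stopifnot(inherits(table, "abundance_table"))
  rank <- match.arg(rank, c("kingdom", "phylum", "class", "order",
                            "family", "genus"))
  idx <- match(table$feature_ids, tax$feature_id)
  if (anyNA(idx))
    stop("feature(s) missing from the taxonomy map: ",
         paste(utils::head(table$feature_ids[is.na(idx)], 3), collapse = ", "))
  groups <- tax[[rank]][idx]
  if (anyNA(groups))
    stop("feature(s) with no ", rank, " annotation: ",
         paste(utils::head(table$feature_ids[is.na(groups)], 3), collapse = ", "))
  gnames <- sort(unique(groups))
  agg <- matrix(0, nrow(table$values), length(gnames),
                dimnames = list(table$sample_ids, gnames))
  for (g in gnames)
    agg[, g] <- rowSums(table$values[, groups == g, drop = FALSE])
  suppressWarnings(abundance_table(agg, table$sample_ids, gnames))
}

#' Harmonize two studies' feature groups at a taxonomic rank
#'
#' Intersects the group-name inventories of two studies; the overlap,
#' sorted lexicographically, becomes the shared column order applied to
#' both, and the non-overlapping groups are dropped.
#'
#' @param groups_A,groups_B character vectors of group names.
#' @param rank the rank the names belong to (recorded in the report).
#' @return an object of class `harmonization_report` with `rank`,
#'   `groups_A`, `groups_B`, `overlap` (the retained shared order),
#'   `dropped_A` and `dropped_B`.
#' @export
harmonize <- function(groups_A, groups_B, rank = "phylum") {
  groups_A <- unique(as.character(groups_A))
  groups_B <- unique(as.character(groups_B))
  if (length(groups_A) == 0 || length(groups_B) == 0)
    stop("group sets must be non-empty")
  overlap <- sort(intersect(groups_A, groups_B))
  if (length(overlap) == 0)
    stop("no overlapping ", rank, " groups: transfer impossible")
  structure(list(rank = rank, groups_A = groups_A, groups_B = groups_B,
                 overlap = overlap,
                 retained = overlap,
                 dropped_A = sort(setdiff(groups_A, overlap)),
                 dropped_B = sort(setdiff(groups_B, overlap))),
            class = "harmonization_report")
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat(sprintf("harmonization at %s: %d/%d (A) and %d/%d (B) groups retained\n",
              x$rank, length(x$overlap), length(x$groups_A),
              length(x$overlap), length(x$groups_B)))
  if (length(x$dropped_A) + length(x$dropped_B) > 0)
    cat("  dropped:", paste(union(x$dropped_A, x$dropped_B), collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a harmonization report as JSON
#'
#' @param report a [harmonize()] result.
#' @param path output file.
#' @export
write_harmonization_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Restrict an abundance table to a harmonized column order
#'
#' @param table an aggregated `abundance_table`.
#' @param report a [harmonize()] result whose `overlap` names columns of
#'   `table`.
#' @return the table restricted to the shared columns, in shared order.
#' @export
apply_harmonization <- function(table, report) {
  miss <- setdiff(report$overlap, table$feature_ids)
  if (length(miss) > 0)
    stop("table lacks harmonized group(s): ", paste(miss, collapse = ", "))
  vals <- table$values[, report$overlap, drop = FALSE]
  suppressWarnings(abundance_table(vals, table$sample_ids, report$overlap))
}

#' Discriminative per-layer learning rates
#'
#' The last layer trains at the base rate; each step toward the input
#' divides the rate by `decay`, so earlier layers (generic features) move
#' less than later ones during fine-tuning.
#'
#' @param base_lr learning rate of the last layer.
#' @param n_layers number of layer blocks, ordered first to last.
#' @param decay geometric decay factor (> 1).
#' @return numeric vector of length `n_layers`, increasing toward the last
#'   layer.
#' @export
discriminative_lrs <- function(base_lr, n_layers, decay = 2.6) {
  if (decay <= 1) stop("decay must be > 1")
  base_lr / decay^((n_layers - 1):0)
}

#' Gradual unfreezing schedule
#'
#' On epoch 1 only the last layer trains; each subsequent epoch unfreezes
#' one more layer from the output toward the input.
#'
#' @param n_layers number of layer blocks.
#' @param epoch current epoch (>= 1).
#' @return integer indices (into 1..n_layers, last = output) of the
#'   trainable layers.
#' @export
unfreeze_schedule <- function(n_layers, epoch) {
  if (epoch < 1) stop("epoch must be >= 1")
  k <- min(epoch, n_layers)
  seq.int(n_layers - k + 1L, n_layers)
}

#' Fine-tune a trained model on a second study
#'
#' Loads the body weights (convolutional stack and recurrent cell) of a
#' source-study model, replaces the classifier head by a freshly
#' initialized concat-pooling head sized to the target outcome, and trains
#' on the target batch with discriminative per-block learning rates and
#' gradual unfreezing. Source and target must share an identical harmonized
#' feature order.
#'
#' @param source a fitted `ld_model` (trained on the harmonized features).
#' @param target_batch a `padded_batch` over the same harmonized features.
#' @param epochs fine-tuning epochs.
#' @param base_lr learning rate of the head (deepest block).
#' @param decay discriminative decay between blocks.
#' @param valid_batch optional held-out target batch.
#' @param seed RNG seed for head initialization and shuffling.
#' @param freeze_body if TRUE the body is never unfrozen (head-only tuning).
#' @return an `ld_model` fitted to the target study.
#' @export
transfer_fit <- function(source, target_batch, epochs = 20, base_lr = 1e-3,
                         decay = 2.6, valid_batch = NULL, seed = 1L,
                         freeze_body = FALSE) {
  stopifnot(inherits(source, "ld_model"), inherits(target_batch, "padded_batch"))
  if (length(source$feature_ids) != length(target_batch$feature_ids))
    stop("feature spaces differ in size; harmonize both studies first")
  mism <- which(source$feature_ids != target_batch$feature_ids)
  if (length(mism) > 0)
    stop("feature order mismatch at position ", mism[1], ": '",
         source$feature_ids[mism[1]], "' vs '",
         target_batch$feature_ids[mism[1]], "'")
  cfg <- source$config
  cfg$concat_pool <- TRUE
  cfg$epochs <- epochs
  cfg$lr <- base_lr
  n_out <- length(target_batch$label_levels)
  H <- source$params$meta$hidden_size
  set.seed(seed)
  head <- head_parameters(3 * H, cfg$head_hidden, n_out)
  mp <- source$params
  mp$head <- head
  mp$branches <- NULL
  mp$meta$n_out <- n_out
  mp$meta$multi_label <- target_batch$multi_label
  mp$meta$concat_pool <- TRUE
  blocks <- c(if (!is.null(mp$conv)) "conv", "cell", "head")
  lrs <- discriminative_lrs(1, length(blocks), decay)  # relative scales
  block_scale <- stats::setNames(as.list(lrs), blocks)
  if (freeze_body) {
    for (b in setdiff(blocks, "head")) block_scale[[b]] <- 0
  }
  tr <- train_network(mp, target_batch, scheme = "none", config = cfg,
                      valid_batch = valid_batch,
                      use_mask = identical(target_batch$strategy_tag,
                                           "pad_at_end"),
                      seed = seed + 20011L,
                      block_scale = block_scale,
                      unfreeze = !freeze_body)
  structure(list(params = tr$params, best_params = tr$best_params,
                 trace = tr$trace, model = source$model, distill = "none",
                 config = cfg,
                 use_mask = identical(target_batch$strategy_tag, "pad_at_end"),
                 ae = NULL,
                 label_levels = target_batch$label_levels,
                 multi_label = target_batch$multi_label,
                 strategy = target_batch$strategy_tag,
                 feature_ids = target_batch$feature_ids,
                 input_features = dim(target_batch$values)[3],
                 seed = seed, transferred_from = source$seed),
            class = "ld_model")
}
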