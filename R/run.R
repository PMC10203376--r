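## Experiment driver tying the pipeline together: generate or load data,
## preprocess, train under a chosen scheme, evaluate by cross-validation and
## write a results directory (fold CSV, summary JSON, loss traces, config
## copy, log). The exported functions are the package's command surface;
## the thin script in inst/cli wraps them for shell use.

#' Experiment configuration
#'
#' Collects everything one run needs. Data come either from a
#' [synth_config()] (`synth`) or from file paths (`abundance`, `metadata`,
#' `canonical_grid`, optional `taxonomy`).
#'
#' @param model one of `"lstm"`, `"cnnlstm"`, `"rnn"`, `"ulstm"`.
#' @param distill `"none"`, `"fd"` or `"sd"` (forbidden for `"ulstm"`).
#' @param strategy `"pad_in_sequence"` or `"pad_at_end"`.
#' @param pca logical; `n_components` retained when on.
#' @param k cross-validation folds.
#' @param seed master seed.
#' @param synth optional [synth_config()].
#' @param abundance,metadata,taxonomy,label_cols,canonical_grid file-based
#'   inputs (used when `synth` is NULL).
#' @param net a [net_config()] list.
#' @return a list of class `run_config`.
#' @export
run_config <- function(model = "cnnlstm", distill = "none",
                       strategy = "pad_in_sequence", pca = FALSE,
                       n_components = 300, k = 10, seed = 1L,
                       synth = NULL, abundance = NULL, metadata = NULL,
                       taxonomy = NULL, label_cols = "label",
                       canonical_grid = NULL, net = net_config()) {
  if (model == "ulstm" && distill != "none")
    stop("config error: the autoencoder baseline forbids distillation")
  structure(as.list(environment()), class = "run_config")
}

# FNV-1a hash of the deparsed configuration, for run provenance logging.
# 32-bit arithmetic is done in doubles: the xor touches only the low byte and
# the multiply is split at 2^16 so no intermediate exceeds 2^53.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

load_run_cohort <- function(config) {
  if (!is.null(config$synth)) {
    syn <- generate(config$synth)
    assemble_cohort(syn$table, syn$meta, syn$canonical_grid)
  } else {
    if (is.null(config$abundance) || is.null(config$metadata) ||
        is.null(config$canonical_grid))
      stop("config error: need either synth or abundance+metadata+canonical_grid")
    tab <- load_abundance_table(config$abundance)
    meta <- load_sample_metadata(config$metadata,
                                 label_cols = config$label_cols)
    assemble_cohort(tab, meta, config$canonical_grid)
  }
}

#' Run one experiment end to end
#'
#' Generates or loads the cohort, runs the cross-validated training and
#' evaluation of the configured model, and writes the results directory:
#' `fold_metrics.csv`, `summary.json`, `config.json` and `run.log`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return the [cross_validate()] result, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  log_line("longidistill %s | seed %d | config %s",
           as.character(utils::packageVersion("longidistill")),
           config$seed, config_hash(config))
  log_line("stage: load (seed %d)", config$seed)
  cohort <- load_run_cohort(config)
  log_line("cohort: %d subjects, %d features", length(cohort$subjects),
           length(cohort$feature_ids))
  log_line("stage: cross-validate (%s / %s / %s, k=%d)",
           config$model, config$distill, config$strategy, config$k)
  cv <- cross_validate(cohort, model = config$model,
                       distill = config$distill,
                       strategy = config$strategy, pca = config$pca,
                       n_components = config$n_components, k = config$k,
                       seed = config$seed, config = config$net)
  utils::write.csv(cv$folds, file.path(out_dir, "fold_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(summary = as.list(cv$summary),
                            settings = cv$settings),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg_out <- config
  cfg_out$net <- config$net[!vapply(config$net, is.list, logical(1))]
  jsonlite::write_json(lapply(unclass(cfg_out), function(x)
                         if (inherits(x, "synth_config")) unclass(x) else x),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("done: AUC %.3f +/- %.3f", cv$summary["auc_mean"],
           cv$summary["auc_sd"])
  invisible(cv)
}

#' Run the sparse-autoencoder LSTM baseline
#'
#' Convenience wrapper: forces `model = "ulstm"` (two-stage run: the sparse
#' autoencoder is trained on the observed vectors, its encoder frozen, and
#' the latent codes fed per time point into the LSTM classifier) and
#' evaluates identically to the other models.
#'
#' @param config a [run_config()]; its model field is overridden.
#' @param out_dir output directory.
#' @export
run_ulstm_baseline <- function(config, out_dir) {
  config$model <- "ulstm"
  config$distill <- "none"
  run_experiment(config, out_dir)
}

#' Run a grid of experiments
#'
#' One results subdirectory per cell of models x padding strategies x PCA
#' settings, mirroring the study's comparison layout.
#'
#' @param base a [run_config()] used as template.
#' @param out_dir parent output directory.
#' @param models,strategies,pca_opts grid axes.
#' @return named list of [cross_validate()] results.
#' @export
run_grid <- function(base, out_dir, models = c("lstm", "cnnlstm"),
                     strategies = c("pad_in_sequence", "pad_at_end"),
                     pca_opts = c(FALSE, TRUE)) {
  res <- list()
  for (m in models) for (s in strategies) for (p in pca_opts) {
    cfg <- base
    cfg$model <- m; cfg$strategy <- s; cfg$pca <- p
    tag <- sprintf("%s_%s_%s", m, s, if (p) "pca" else "raw")
    res[[tag]] <- run_experiment(cfg, file.path(out_dir, tag))
  }
  res
}

#' Save / load a fitted model checkpoint
#'
#' Checkpoints carry the full parameter set plus architecture metadata
#' (shapes, padding strategy, seed) so the transfer module can load or
#' partially load them.
#'
#' @param model an `ld_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ld_model"))
  m
}

#' Serialize a padded batch to a portable JSON container
#'
#' Datasets `values`, `mask` and `labels` plus the attributes
#' `strategy_tag` and `canonical_grid`, mirroring an HDF5-style layout in
#' plain text.
#'
#' @param batch a `padded_batch`.
#' @param path output file.
#' @export
save_padded_batch <- function(batch, path) {
  d <- dim(batch$values)
  obj <- list(values = batch$values, mask = batch$mask,
              labels = if (batch$multi_label) batch$labels
                       else as.character(batch$labels),
              dim = d, subject_ids = batch$subject_ids,
              feature_ids = batch$feature_ids,
              label_levels = batch$label_levels,
              multi_label = batch$multi_label,
              strategy_tag = batch$strategy_tag,
              canonical_grid = batch$canonical_grid)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_padded_batch
#' @export
load_padded_batch <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- if (o$multi_label) as.matrix(o$labels)
            else factor(o$labels, levels = o$label_levels)
  new_padded_batch(o$values, as.matrix(o$mask), labels, o$subject_ids,
                   o$strategy_tag, o$canonical_grid, o$label_levels,
                   o$multi_label, o$feature_ids)
}
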