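## Synthetic longitudinal cohort generator: compositional abundance profiles
## with class-dependent temporal drift on a subset of taxa, missing time
## points, class imbalance and a consistent 6-rank taxonomy, so the whole
## pipeline is testable without any download.

#' Synthetic cohort configuration
#'
#' Describes the generative model: each subject draws a baseline composition
#' from a Dirichlet distribution; at time step t (0-based slot index) the
#' signal taxa of a subject in class k are multiplied by
#' `exp(effect_size * t * d_k)` with per-class drift direction `d_k` spaced
#' evenly in \[0, 1\] (class 1 is the no-drift reference, matching a
#' severity gradient); multiplicative log-normal sampling noise is applied
#' and the profile renormalized to sum 1. Non-initial time points are
#' dropped independently with probability `missing_rate`; the first time
#' point is never dropped.
#'
#' @param n_subjects,n_features,n_timepoints cohort dimensions.
#' @param n_classes number of mutually exclusive outcome classes (ignored in
#'   multi-label mode).
#' @param multi_label logical; generate independent binary outcome labels.
#' @param n_labels number of binary labels in multi-label mode.
#' @param label_prevalence per-label positive rates in multi-label mode.
#' @param signal_taxa_fraction fraction of taxa carrying the class signal.
#' @param effect_size per-time-step log-abundance drift of the signal taxa.
#' @param missing_rate per-(subject, non-initial time point) drop
#'   probability, in \[0, 1).
#' @param class_weights sampling probabilities of the classes; the default
#'   is mildly imbalanced (proportional to K, K-1, ..., 1) to emulate the
#'   skewed outcome frequencies of real cohorts.
#' @param concentration Dirichlet base concentration of the baseline
#'   composition (0.5: sparse, microbiome-like profiles).
#' @param noise_sd standard deviation of the per-sample log-normal noise.
#' @param n_phyla number of phyla in the attached taxonomy.
#' @param phylum_names optional explicit phylum names (length `n_phyla`).
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 200, n_features = 100,
                         n_timepoints = 4, n_classes = 2,
                         multi_label = FALSE, n_labels = 3,
                         label_prevalence = rep(0.25, n_labels),
                         signal_taxa_fraction = 0.1, effect_size = 0.5,
                         missing_rate = 0.2, class_weights = NULL,
                         concentration = 0.5, noise_sd = 0.3,
                         n_phyla = 6, phylum_names = NULL, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (is.null(class_weights))
    class_weights <- rev(seq_len(n_classes)) / sum(seq_len(n_classes))
  if (abs(sum(class_weights) - 1) > 1e-8)
    stop("class_weights must sum to 1")
  n_signal <- max(1L, round(signal_taxa_fraction * n_features))
  if (n_signal > n_features)
    stop("signal taxa count exceeds n_features")
  if (!is.null(phylum_names) && length(phylum_names) != n_phyla)
    stop("phylum_names must have length n_phyla")
  structure(as.list(environment()), class = "synth_config")
}

rdirichlet_row <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  g / sum(g)
}

make_lineages <- function(config) {
  Fk <- config$n_features
  phyla <- if (is.null(config$phylum_names))
             sprintf("Phylum%02d", seq_len(config$n_phyla))
           else config$phylum_names
  # every phylum is represented at least once
  assign <- c(seq_len(config$n_phyla),
              sample.int(config$n_phyla, max(0, Fk - config$n_phyla),
                         replace = TRUE))
  assign <- assign[sample.int(length(assign))][seq_len(Fk)]
  deepen <- function(parent, n_children, tag) {
    paste0(parent, "_", tag, sample.int(n_children, length(parent),
                                        replace = TRUE))
  }
  phylum <- phyla[assign]
  class_ <- deepen(phylum, 2, "c")
  order_ <- deepen(class_, 2, "o")
  family <- deepen(order_, 2, "f")
  genus <- deepen(family, 2, "g")
  data.frame(feature_id = sprintf("OTU%04d", seq_len(Fk)),
             kingdom = "Bacteria", phylum = phylum, class = class_,
             order = order_, family = family, genus = genus,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort under the generative model described in [synth_config()]
#' and returns the same table trio the loaders consume: an abundance table,
#' a sample metadata table and a taxonomy map.
#'
#' @param config a [synth_config()].
#' @return list with `table` ([abundance_table()]), `meta`
#'   ([sample_metadata()]), `taxonomy` (data.frame of 6-rank lineages) and
#'   `canonical_grid` (0-based time slots).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_subjects; Fk <- config$n_features; Tn <- config$n_timepoints
  taxonomy <- make_lineages(config)
  n_signal <- max(1L, round(config$signal_taxa_fraction * Fk))
  if (config$multi_label) {
    L <- config$n_labels
    lab_mat <- matrix(0, n, L)
    for (l in seq_len(L))
      lab_mat[, l] <- stats::rbinom(n, 1, config$label_prevalence[l])
    signal_sets <- lapply(seq_len(L), function(l) sample.int(Fk, n_signal))
    label_names <- sprintf("label%d", seq_len(L))
    colnames(lab_mat) <- label_names
  } else {
    K <- config$n_classes
    cls <- sample.int(K, n, replace = TRUE, prob = config$class_weights)
    drift_dir <- if (K > 1) (seq_len(K) - 1) / (K - 1) else 0
    signal_taxa <- sample.int(Fk, n_signal)
  }
  rows <- list(); meta_rows <- list()
  for (i in seq_len(n)) {
    base <- rdirichlet_row(Fk, config$concentration)
    kept <- if (Tn > 1)
              c(0L, which(stats::runif(Tn - 1) >= config$missing_rate))
            else 0L
    for (t in 0:(Tn - 1)) {
      x <- base
      if (config$multi_label) {
        for (l in which(lab_mat[i, ] == 1))
          x[signal_sets[[l]]] <- x[signal_sets[[l]]] *
            exp(config$effect_size * t)
      } else {
        x[signal_taxa] <- x[signal_taxa] *
          exp(config$effect_size * t * drift_dir[cls[i]])
      }
      x <- x * exp(stats::rnorm(Fk, 0, config$noise_sd))
      x <- x / sum(x)
      if (!(t %in% kept)) next
      sid <- sprintf("S%04d", i)
      rows[[length(rows) + 1]] <- x
      mr <- data.frame(sample_id = sprintf("%s_t%d", sid, t),
                       subject_id = sid, time_point = t,
                       stringsAsFactors = FALSE)
      if (config$multi_label) {
        mr <- cbind(mr, as.data.frame(t(lab_mat[i, ])))
      } else {
        mr$label <- sprintf("class%d", cls[i])
      }
      meta_rows[[length(meta_rows) + 1]] <- mr
    }
  }
  meta <- do.call(rbind, meta_rows)
  values <- do.call(rbind, rows)
  table <- abundance_table(values, meta$sample_id, taxonomy$feature_id)
  label_cols <- if (config$multi_label) colnames(lab_mat) else "label"
  list(table = table,
       meta = sample_metadata(meta, label_cols = label_cols),
       taxonomy = taxonomy,
       canonical_grid = 0:(Tn - 1),
       config = config)
}

#' Generate two studies with partially overlapping taxonomies
#'
#' Builds a pair of synthetic cohorts whose phylum inventories share exactly
#' `shared_phyla` names, the fixture for cross-study harmonization: running
#' [harmonize()] on their phylum sets yields an overlap of that size.
#'
#' @param config_A,config_B [synth_config()]s for the two studies (their
#'   `n_phyla` must be >= `shared_phyla`).
#' @param shared_phyla number of phylum names common to both studies.
#' @return list with elements `A` and `B`, each a [generate()] result.
#' @export
make_paired_studies <- function(config_A, config_B, shared_phyla) {
  if (shared_phyla > config_A$n_phyla || shared_phyla > config_B$n_phyla)
    stop("shared_phyla exceeds a study's phylum count")
  shared <- sprintf("SharedPhylum%02d", seq_len(shared_phyla))
  config_A$phylum_names <- c(shared,
    sprintf("StudyAPhylum%02d", seq_len(config_A$n_phyla - shared_phyla)))
  config_B$phylum_names <- c(shared,
    sprintf("StudyBPhylum%02d", seq_len(config_B$n_phyla - shared_phyla)))
  list(A = generate(config_A), B = generate(config_B))
}

#' Write a generated cohort as the TSV trio the loaders consume
#'
#' Each file starts with a comment header recording the generating seed; the
#' loaders skip `#`-prefixed lines.
#'
#' @param syn a [generate()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort_tsv <- function(syn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- if (is.null(syn$config)) "# synthetic cohort"
         else sprintf("# synthetic cohort; seed: %d", syn$config$seed)
  emit <- function(df, path) {
    writeLines(hdr, path)
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
  }
  ab <- file.path(dir, "abundance.tsv")
  df <- data.frame(sample_id = syn$table$sample_ids,
                   syn$table$values, check.names = FALSE)
  colnames(df) <- c("sample_id", syn$table$feature_ids)
  emit(df, ab)
  me <- file.path(dir, "metadata.tsv")
  emit(as.data.frame(syn$meta), me)
  tx <- file.path(dir, "taxonomy.tsv")
  lin <- apply(syn$taxonomy[, -1], 1, function(r)
    paste(paste0(c("k__", "p__", "c__", "o__", "f__", "g__"), r),
          collapse = "; "))
  emit(data.frame(feature_id = syn$taxonomy$feature_id, lineage = lin), tx)
  invisible(c(abundance = ab, metadata = me, taxonomy = tx))
}

#' Read / write a synthetic-cohort configuration as YAML
#'
#' Round-trips every [synth_config()] field; requires the suggested `yaml`
#' package.
#'
#' @param config a [synth_config()].
#' @param path YAML file path.
#' @return `write_synth_yaml`: the path, invisibly; `read_synth_yaml`: a
#'   [synth_config()].
#' @export
write_synth_yaml <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML configs")
  stopifnot(inherits(config, "synth_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_synth_yaml
#' @export
read_synth_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML configs")
  vals <- yaml::read_yaml(path)
  do.call(synth_config, vals[setdiff(names(vals), "n_signal")])
}
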