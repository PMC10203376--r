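#' Construct an abundance table
#'
#' A relative-abundance table holds one row per sample and one column per
#' taxon (OTU or aggregated rank). Values are unitless fractions; each row is
#' expected to sum to 1 because upstream pipelines emit pre-normalized
#' profiles. Deviations beyond `tol` raise a warning, not an error, since
#' rounding during export routinely perturbs row sums.
#'
#' @param values numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_ids character vector of unique taxon identifiers.
#' @param tol allowed absolute deviation of each row sum from 1.
#' @return an object of class `abundance_table` with elements `sample_ids`,
#'   `feature_ids` and `values`.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            feature_ids = colnames(values), tol = 1e-3) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match row count")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length does not match column count")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1])
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ", feature_ids[duplicated(feature_ids)][1])
  if (nrow(values) > 0) {
    if (any(!is.finite(values)))
      stop("abundance values must be finite")
    if (any(values < 0))
      stop("abundance values must be non-negative")
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > tol)
    if (length(bad) > 0)
      warning(sprintf("%d row(s) deviate from unit sum (first: sample '%s', sum %.5g)",
                      length(bad), sample_ids[bad[1]], rs[bad[1]]))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(sample_ids = sample_ids, feature_ids = feature_ids,
                 values = values),
            class = "abundance_table")
}

#' Read an abundance table from delimited text
#'
#' The first row must be a feature header and the first column the sample
#' identifier. All remaining cells must parse as numbers.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter field separator; `"\t"` or `","` (default guesses from
#'   the file extension: `.csv` means comma, anything else tab).
#' @param tol row-sum tolerance passed to [abundance_table()].
#' @return an `abundance_table`.
#' @export
load_abundance_table <- function(path, delimiter = NULL, tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, row.names = NULL,
                           comment.char = "#")
  if (ncol(raw) < 1) stop("no columns parsed from ", path)
  feature_ids <- colnames(raw)[-1]
  sample_ids <- as.character(raw[[1]])
  if (nrow(raw) == 0) {
    return(abundance_table(matrix(numeric(0), 0, length(feature_ids)),
                           character(0), feature_ids, tol = tol))
  }
  vals <- matrix(NA_real_, nrow(raw), length(feature_ids))
  for (j in seq_along(feature_ids)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(col) & !is.na(raw[[j + 1]]) & raw[[j + 1]] != "NA")
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell at row %d (sample '%s'), column '%s': '%s'",
                   bad[1], sample_ids[bad[1]], feature_ids[j],
                   raw[[j + 1]][bad[1]]))
    vals[, j] <- col
  }
  abundance_table(vals, sample_ids, feature_ids, tol = tol)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features\n",
              length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' Read a sample metadata table
#'
#' Metadata maps each sample to a subject, an ordinal time point and the
#' subject's outcome label(s). For the mutually exclusive outcome mode a
#' single `label` column is used; for the multi-label mode, one 0/1 column
#' per outcome.
#'
#' @param path path to a TSV/CSV file with columns `sample_id`,
#'   `subject_id`, `time_point` and either `label` or the columns named in
#'   `label_cols`.
#' @param delimiter field separator (guessed from the extension by default).
#' @param label_cols character vector of label column names; default
#'   `"label"`.
#' @return a data.frame of class `sample_metadata`.
#' @export
load_sample_metadata <- function(path, delimiter = NULL, label_cols = "label") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meta <- utils::read.table(path, sep = delimiter, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
  sample_metadata(meta, label_cols = label_cols)
}

#' Validate a metadata data.frame
#'
#' @param meta data.frame with columns `sample_id`, `subject_id`,
#'   `time_point` and the label column(s).
#' @param label_cols names of the label column(s).
#' @return the validated data.frame, classed `sample_metadata` with the
#'   label columns recorded in attribute `label_cols`.
#' @export
sample_metadata <- function(meta, label_cols = "label") {
  need <- c("sample_id", "subject_id", "time_point", label_cols)
  miss <- setdiff(need, colnames(meta))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$subject_id <- as.character(meta$subject_id)
  meta$time_point <- as.numeric(meta$time_point)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1])
  key <- paste(meta$subject_id, meta$time_point, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate (subject, time_point) pair: (%s, %s)",
                 meta$subject_id[d], meta$time_point[d]))
  }
  attr(meta, "label_cols") <- label_cols
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' Read an abundance table from a BIOM file
#'
#' Thin adapter over the `biomformat` package (suggested dependency):
#' observations (taxa) become columns and samples rows, matching
#' [load_abundance_table()]'s contract.
#'
#' @param path path to a BIOM file (JSON or HDF5 variant, as supported by
#'   `biomformat`).
#' @param tol row-sum tolerance passed to [abundance_table()].
#' @return an `abundance_table`.
#' @export
load_abundance_biom <- function(path, tol = 1e-3) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
  abundance_table(t(m), colnames(m), rownames(m), tol = tol)
}
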