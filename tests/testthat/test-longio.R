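# Tables, metadata, cohort assembly, padding strategies, PCA reduction.

test_that("abundance_table validates and a 2x3 CSV parses", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,A,B,C", "s1,0.2,0.3,0.5", "s2,0.1,0.1,0.8"), f)
  tab <- load_abundance_table(f)
  expect_s3_class(tab, "abundance_table")
  expect_equal(dim(tab$values), c(2L, 3L))
  expect_equal(tab$sample_ids, c("s1", "s2"))
  expect_equal(tab$feature_ids, c("A", "B", "C"))
  expect_equal(unname(tab$values[1, ]), c(0.2, 0.3, 0.5))
})

test_that("row-sum deviations warn but do not fail", {
  expect_warning(
    abundance_table(matrix(c(0.2, 0.2, 0.2), 1, 3), "s1", c("A", "B", "C")),
    "deviate from unit sum")
})

test_that("header-only file yields an empty table", {
  f <- tempfile(fileext = ".tsv")
  writeLines("sample_id\tA\tB", f)
  tab <- load_abundance_table(f)
  expect_equal(length(tab$sample_ids), 0L)
  expect_equal(tab$feature_ids, c("A", "B"))
})

test_that("non-numeric cells and duplicate ids are rejected with context", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB", "s1\t0.5\toops"), f)
  expect_error(load_abundance_table(f), "row 1.*column 'B'.*oops")
  expect_error(
    suppressWarnings(abundance_table(matrix(0.5, 2, 2), c("s1", "s1"),
                                     c("A", "B"))),
    "duplicate sample id")
  expect_error(
    suppressWarnings(abundance_table(matrix(0.5, 1, 2), "s1", c("A", "A"))),
    "duplicate feature id")
  expect_error(abundance_table(matrix(-0.1, 1, 1), "s1", "A"),
               "non-negative")
})

test_that("sample_metadata enforces uniqueness invariants", {
  ok <- data.frame(sample_id = c("a", "b"), subject_id = c("s", "s"),
                   time_point = c(0, 4), label = "x")
  expect_s3_class(sample_metadata(ok), "sample_metadata")
  dup_sample <- ok; dup_sample$sample_id <- c("a", "a")
  expect_error(sample_metadata(dup_sample), "duplicate sample_id")
  dup_pair <- ok; dup_pair$time_point <- c(0, 0)
  expect_error(sample_metadata(dup_pair), "duplicate \\(subject, time_point\\)")
  expect_error(sample_metadata(ok[, 1:3]), "missing column")
})

test_that("assemble_cohort builds ordered subjects on the grid", {
  vals <- matrix(1 / 3, 4, 3)
  tab <- abundance_table(vals, c("p1", "p2", "q1", "q2"), c("A", "B", "C"))
  meta <- data.frame(sample_id = c("p1", "p2", "q1", "q2"),
                     subject_id = c("P", "P", "Q", "Q"),
                     time_point = c(0, 4, 52, 0), label = c("x", "x", "y", "y"))
  coh <- assemble_cohort(tab, meta, canonical_grid = c(0, 4, 12, 52))
  expect_length(coh$subjects, 2)
  expect_equal(vapply(coh$subjects, function(s) length(s$times), integer(1)),
               c(2L, 2L))
  # file order week 52 then 0 is re-sorted
  expect_equal(coh$subjects[[2]]$times, c(0, 52))
})

test_that("off-grid samples and conflicting labels error", {
  tab <- abundance_table(matrix(1 / 2, 2, 2), c("a", "b"), c("A", "B"))
  off <- data.frame(sample_id = c("a", "b"), subject_id = "s",
                    time_point = c(0, 7), label = "x")
  expect_error(assemble_cohort(tab, off, c(0, 4, 12, 52)),
               "off the canonical grid.*'b' at 7")
  conf <- data.frame(sample_id = c("a", "b"), subject_id = "s",
                     time_point = c(0, 4), label = c("x", "y"))
  expect_error(assemble_cohort(tab, conf, c(0, 4, 12, 52)),
               "conflicting labels")
})

test_that("pad_in_sequence reproduces the published worked example", {
  batch <- pad_in_sequence(table1_cohort())
  expect_equal(dim(batch$values), c(1L, 4L, 4L))
  expect_equal(unname(batch$mask[1, ]), c(1, 0, 0, 1))
  expect_equal(unname(batch$values[1, 1, ]), table1_week0)
  expect_true(all(batch$values[1, 2:3, ] == 0))
  expect_equal(unname(batch$values[1, 4, ]), table1_week52)
})

test_that("fully observed subjects are identity under both paddings", {
  coh <- small_cohort(n = 10, Fk = 6, seed = 5, missing_rate = 0)
  a <- pad_in_sequence(coh)
  b <- pad_at_end(coh, use_grid_length = TRUE)
  expect_true(all(a$mask == 1))
  expect_equal(a$values, b$values)
})

test_that("pad_at_end compacts observations to a ones-prefix mask", {
  batch <- pad_at_end(table1_cohort(), use_grid_length = TRUE)
  expect_equal(unname(batch$mask[1, ]), c(1, 1, 0, 0))
  expect_equal(unname(batch$values[1, 1, ]), table1_week0)
  expect_equal(unname(batch$values[1, 2, ]), table1_week52)
  expect_true(all(batch$values[1, 3:4, ] == 0))
  # default T_slots is the max observation count
  expect_equal(dim(pad_at_end(table1_cohort())$values)[2], 2L)
})

test_that("padded values at mask-0 positions are exactly zero", {
  coh <- small_cohort(n = 25, Fk = 8, seed = 9, missing_rate = 0.4)
  for (batch in list(pad_in_sequence(coh), pad_at_end(coh))) {
    off <- which(batch$mask == 0, arr.ind = TRUE)
    for (r in seq_len(nrow(off)))
      expect_true(all(batch$values[off[r, 1], off[r, 2], ] == 0))
  }
})

test_that("full-rank PCA reconstructs centered data", {
  set.seed(1)
  X <- matrix(rnorm(40 * 6), 40, 6)
  mp <- fit_pca(X, n_components = 6)
  proj <- longidistill:::pca_project(mp, X)
  recon <- proj %*% t(mp$rotation)
  centered <- sweep(X, 2, mp$center)
  expect_lt(max(abs(recon - centered)), 1e-8)
})

test_that("apply_pca keeps padded rows at zero and renames features", {
  coh <- small_cohort(n = 20, Fk = 10, seed = 4, missing_rate = 0.4)
  batch <- pad_in_sequence(coh)
  mp <- fit_pca(longidistill:::observed_rows(batch), n_components = 3)
  out <- apply_pca(mp, batch)
  expect_equal(dim(out$values)[3], 3L)
  expect_equal(out$feature_ids, c("PC1", "PC2", "PC3"))
  off <- which(out$mask == 0, arr.ind = TRUE)
  for (r in seq_len(nrow(off)))
    expect_true(all(out$values[off[r, 1], off[r, 2], ] == 0))
})

test_that("fit_pca matches prcomp and bounds n_components", {
  set.seed(2)
  X <- matrix(rnorm(15 * 8), 15, 8)
  mp <- fit_pca(X, 4)
  pc <- stats::prcomp(X, center = TRUE)
  expect_equal(abs(mp$rotation), abs(pc$rotation[, 1:4]), tolerance = 1e-10)
  expect_error(fit_pca(X, 9), "exceeds min\\(n_rows=15, n_features=8\\)")
})

test_that("truncate_history keeps each subject's first observations", {
  coh <- small_cohort(n = 12, Fk = 5, seed = 3, missing_rate = 0.3)
  tr <- truncate_history(coh, 2)
  for (s in tr$subjects) expect_lte(length(s$times), 2L)
  full <- truncate_history(coh, length(coh$canonical_grid))
  expect_equal(full, coh)
  expect_error(truncate_history(coh, 0), "horizon")
})

test_that("subset_batch keeps values, mask and labels aligned", {
  coh <- small_cohort(n = 15, Fk = 5, seed = 8)
  batch <- pad_in_sequence(coh)
  sub <- subset_batch(batch, c(3, 7))
  expect_equal(sub$subject_ids, batch$subject_ids[c(3, 7)])
  expect_equal(sub$values[2, , ], batch$values[7, , ])
  expect_equal(as.character(sub$labels), as.character(batch$labels[c(3, 7)]))
})
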