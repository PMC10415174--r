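test_that("contaminant removal drops flagged proteins and is idempotent", {
  ds <- make_ds(matrix(1:10, 2, 5),
                contaminant = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  out <- remove_contaminants(ds)
  expect_equal(ncol(out$mat), 3)
  expect_equal(out$log[[1]]$n_removed_or_imputed, 2)
  again <- remove_contaminants(out)
  expect_identical(again$mat, out$mat)
  expect_equal(again$log[[2]]$n_removed_or_imputed, 0)
})

test_that("zero-to-missing converts exact zeros only", {
  ds <- make_ds(matrix(c(0, 2, 1, 3), 2, 2))
  out <- zero_to_missing(ds)
  expect_equal(sum(is.na(out$mat)), 1)
  expect_true(is.na(out$mat[1, 1]))
  expect_equal(out$log[[1]]$n_removed_or_imputed, 1)
  # no zeros: unchanged; an all-zero protein becomes all-missing but is kept
  expect_identical(zero_to_missing(make_ds(matrix(1:4, 2, 2)))$mat,
                   make_ds(matrix(1:4, 2, 2))$mat)
  allz <- zero_to_missing(make_ds(cbind(c(0, 0), c(1, 2))))
  expect_equal(ncol(allz$mat), 2)
  expect_true(all(is.na(allz$mat[, 1])))
})

test_that("completeness filter uses the ceiling rule", {
  m <- matrix(1, 4, 3)
  m[c(1, 2), 2] <- NA        # protein 2 observed in 2 of 4
  m[1:3, 3] <- NA            # protein 3 observed in 1 of 4
  ds <- make_ds(m)
  expect_equal(ncol(filter_completeness(ds, 1.0)$mat), 1)
  expect_equal(ncol(filter_completeness(ds, 0.0)$mat), 3)
  # ceil(0.6*4) = 3 > 2 observed -> protein 2 dropped
  expect_equal(ncol(filter_completeness(ds, 0.6)$mat), 1)
  expect_equal(ncol(filter_completeness(ds, 0.5)$mat), 2)
  expect_error(filter_completeness(ds, 1.5), "0, 1")
})

test_that("log2 transform maps values, keeps missing, and guards zeros", {
  ds <- make_ds(matrix(c(8, 2, NA, 4), 2, 2))
  out <- log2_transform(ds)
  expect_equal(out$mat[1, 1], 3)
  expect_true(is.na(out$mat[1, 2]))
  expect_error(log2_transform(make_ds(matrix(c(0, 1, 2, 3), 2, 2))),
               "zero_to_missing")
})

test_that("median centering equalises sample medians at the grand median", {
  m <- rbind(c(8, 10, 12), c(10, 12, 14)) # medians 10 and 12
  out <- normalize_intensities(make_ds(m), "median_center")
  med <- apply(out$mat, 1, median)
  expect_equal(unname(med), c(11, 11))
})

test_that("quantile normalization matches the rank/mean definition", {
  # brute-force case: samples (1,2,3) and (4,5,6) -> both (2.5,3.5,4.5)
  out <- normalize_intensities(make_ds(rbind(1:3, 4:6)), "quantile")
  expect_equal(unname(out$mat), rbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  # complete samples end with identical sorted values (random case)
  set.seed(1)
  m <- matrix(rnorm(5 * 20), 5, 20)
  qn <- normalize_intensities(make_ds(m), "quantile")
  sorted <- apply(qn$mat, 1, sort)
  for (i in 2:5) expect_equal(sorted[, i], sorted[, 1], tolerance = 1e-9)

  # ties get the mean of their ranks' reference values
  m2 <- rbind(c(1, 1, 3), c(4, 5, 6))
  qn2 <- normalize_intensities(make_ds(m2), "quantile")
  ref <- c(mean(c(1, 4)), mean(c(1, 5)), mean(c(3, 6)))
  expect_equal(unname(qn2$mat[1, ]),
               c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))

  # missing cells stay missing and identical samples stay identical
  m3 <- rbind(c(1, 2, NA), c(1, 2, NA))
  qn3 <- normalize_intensities(make_ds(m3), "quantile")
  expect_identical(qn3$mat[1, ], qn3$mat[2, ])
  expect_true(is.na(qn3$mat[1, 3]))
})

test_that("zscore normalization yields observed mean 0 and sd 1 per sample", {
  set.seed(2)
  m <- matrix(rnorm(4 * 10, mean = 20), 4, 10)
  m[2, 3] <- NA
  out <- normalize_intensities(make_ds(m), "zscore")
  expect_true(all(abs(rowMeans(out$mat, na.rm = TRUE)) < 1e-9))
  expect_true(all(abs(apply(out$mat, 1, sd, na.rm = TRUE) - 1) < 1e-9))
  expect_true(is.na(out$mat[2, 3]))
  expect_error(normalize_intensities(make_ds(rbind(c(1, NA), c(1, 2))),
                                     "zscore"), ">= 2 observed")
})

test_that("imputation fills every hole and never touches observed cells", {
  set.seed(3)
  m <- matrix(rnorm(6 * 8, 20), 6, 8)
  holes <- cbind(c(1, 3, 5, 2), c(2, 4, 4, 7))
  m[holes] <- NA
  ds <- make_ds(m, group = rep(c("A", "B"), 3))
  obs <- !is.na(m)
  for (meth in c("mean", "median", "knn", "tree_iterative")) {
    out <- impute_intensities(ds, meth, seed = 5, k = 2)
    expect_false(anyNA(out$mat))
    expect_identical(out$mat[obs], m[obs])
    expect_equal(out$log[[1]]$n_removed_or_imputed, 4)
    # a complete matrix passes through unchanged
    expect_identical(impute_intensities(out, meth, seed = 5, k = 2)$mat,
                     out$mat)
  }
  # per-protein mean: observed (2, 4) -> 3
  m2 <- rbind(c(2, 1), c(4, 1), c(NA, 1))
  got <- impute_intensities(make_ds(m2), "mean")
  expect_equal(got$mat[3, 1], 3)
  expect_equal(impute_intensities(make_ds(m2), "median")$mat[3, 1], 3)

  expect_error(impute_intensities(make_ds(cbind(c(NA, NA), c(1, 2))), "mean"),
               "filter_completeness")
  expect_error(impute_intensities(ds, "knn", k = 6), "k < n_samples")
})

test_that("knn imputation equals an exhaustive nearest-neighbour computation", {
  # 3 samples x 2 proteins, one hole; distances over the shared protein
  m <- rbind(c(1, 10), c(2, 20), c(1.4, NA))
  ds <- make_ds(m)
  out <- impute_intensities(ds, "knn", k = 1)
  # d(S3,S1) = |1.4-1| = 0.4 ; d(S3,S2) = 0.6 -> nearest is S1
  expect_equal(out$mat[3, 2], 10)
  out2 <- impute_intensities(ds, "knn", k = 2)
  expect_equal(out2$mat[3, 2], 15)

  # exhaustive cross-check on a random matrix against a brute-force oracle
  set.seed(8)
  mm <- matrix(rnorm(5 * 6), 5, 6)
  mm[cbind(c(2, 4), c(3, 6))] <- NA
  k <- 2
  got <- impute_intensities(make_ds(mm), "knn", k = k)$mat
  for (cell in list(c(2, 3), c(4, 6))) {
    i <- cell[1]; p <- cell[2]
    d <- sapply(seq_len(5), function(j) {
      if (j == i || is.na(mm[j, p])) return(Inf)
      sh <- !is.na(mm[i, ]) & !is.na(mm[j, ])
      sqrt(sum((mm[i, sh] - mm[j, sh])^2) / sum(sh))
    })
    nb <- order(d)[seq_len(k)]
    expect_equal(got[i, p], mean(mm[nb, p]))
  }
})

test_that("seeded imputation is deterministic for knn and tree ensembles", {
  set.seed(4)
  m <- matrix(rnorm(8 * 12, 20), 8, 12)
  m[sample(length(m), 15)] <- NA
  ds <- make_ds(m)
  for (meth in c("knn", "tree_iterative")) {
    a <- impute_intensities(ds, meth, seed = 99, k = 3)
    b <- impute_intensities(ds, meth, seed = 99, k = 3)
    expect_identical(a$mat, b$mat)
  }
})

test_that("the variant sweep returns one dataset per combination with full logs", {
  set.seed(5)
  m <- matrix(rnorm(6 * 10, 20), 6, 10)
  m[sample(length(m), 6)] <- NA
  ds <- make_ds(m)
  out <- preprocess_variants(ds, c("median_center", "quantile"),
                             c("mean", "knn"), seed = 1, k = 2)
  expect_length(out, 4)
  expect_setequal(names(out),
                  c("median_center+mean", "median_center+knn",
                    "quantile+mean", "quantile+knn"))
  for (v in out) {
    expect_false(anyNA(v$mat))
    expect_equal(vapply(v$log, `[[`, "", "name"), c("normalize", "impute"))
    expect_identical(replay_log(v)$mat, v$mat)
  }
})

test_that("every preprocessing step appends exactly one log entry and is pure", {
  ds <- fixture_dataset(6, 4, seed = 10)
  before <- ds$mat
  steps <- list(
    function(d) remove_contaminants(d),
    function(d) zero_to_missing(d),
    function(d) filter_completeness(d, 0.5),
    function(d) log2_transform(d),
    function(d) normalize_intensities(d, "median_center"),
    function(d) impute_intensities(d, "mean"))
  cur <- ds
  for (i in seq_along(steps)) {
    cur <- steps[[i]](cur)
    expect_length(cur$log, i)
  }
  expect_identical(ds$mat, before)
})
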