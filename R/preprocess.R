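#' Remove contaminant proteins
#'
#' Drops every protein whose contaminant flag is set (see
#' [flag_contaminants()]) and logs the step with the number removed. Calling
#' it again removes nothing.
#'
#' @param ds An [lfq_dataset].
#' @return A new dataset without the flagged proteins.
#' @export
remove_contaminants <- function(ds) {
  stopifnot(inherits(ds, "lfq_dataset"))
  drop <- ds$contaminant
  ds$mat <- ds$mat[, !drop, drop = FALSE]
  ds$contaminant <- ds$contaminant[!drop]
  add_step(ds, "remove_contaminants", list(), sum(drop))
}

#' Convert exact zeros to missing values
#'
#' Search engines report an intensity of 0 when a protein was not quantified
#' in a run; statistically these are missing values, not measurements. This
#' step makes that explicit (and is required before [log2_transform()]).
#'
#' @param ds An [lfq_dataset].
#' @return A new dataset with `0` cells set to `NA`.
#' @export
zero_to_missing <- function(ds) {
  stopifnot(inherits(ds, "lfq_dataset"))
  zero <- !is.na(ds$mat) & ds$mat == 0
  ds$mat[zero] <- NA_real_
  add_step(ds, "zero_to_missing", list(), sum(zero))
}

#' Filter proteins by observation completeness
#'
#' Keeps proteins observed in at least `ceiling(min_fraction * n_samples)`
#' samples. A standard gate before imputation: proteins quantified in too few
#' runs carry no usable group information.
#'
#' @param ds An [lfq_dataset].
#' @param min_fraction Required observed fraction in `[0, 1]`.
#' @return The filtered dataset.
#' @export
filter_completeness <- function(ds, min_fraction) {
  stopifnot(inherits(ds, "lfq_dataset"))
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction > 1) {
    abort("min_fraction must be in [0, 1]")
  }
  need <- ceiling(min_fraction * nrow(ds$mat))
  keep <- colSums(!is.na(ds$mat)) >= need
  ds$mat <- ds$mat[, keep, drop = FALSE]
  ds$contaminant <- ds$contaminant[keep]
  add_step(ds, "filter_completeness", list(min_fraction = min_fraction),
           sum(!keep))
}

#' Log2-transform intensities
#'
#' @param ds An [lfq_dataset]; every observed value must be positive (run
#'   [zero_to_missing()] first).
#' @return The transformed dataset; missing cells stay missing.
#' @export
log2_transform <- function(ds) {
  stopifnot(inherits(ds, "lfq_dataset"))
  if (any(ds$mat <= 0, na.rm = TRUE)) {
    abort(paste0("log2_transform requires positive intensities; ",
                 "convert zeros with zero_to_missing() first"))
  }
  ds$mat <- log2(ds$mat)
  add_step(ds, "log2_transform", list(), sum(!is.na(ds$mat)))
}

#' Normalize sample intensity distributions
#'
#' Scale-location adjustments across samples, computed on observed values
#' only; missing cells remain missing and no protein is reordered.
#'
#' * `median_center`: shifts each sample so its observed median equals the
#'   grand median of the sample medians.
#' * `quantile`: replaces each sample's observed values by the mean order
#'   statistics across samples, so complete samples end up with the identical
#'   sorted value multiset; ties receive the mean of their ranks' reference
#'   values. With missing cells the reference distribution is built from
#'   proteins observed in every sample when any exist, otherwise from
#'   per-rank means over the values available, and each sample is mapped onto
#'   it by rank quantile.
#' * `zscore`: centers each sample's observed values to mean 0, sd 1.
#'
#' Intended for log-scale data (not enforced).
#'
#' @param ds An [lfq_dataset].
#' @param method One of `"median_center"`, `"quantile"`, `"zscore"`.
#' @return The normalized dataset.
#' @export
normalize_intensities <- function(ds, method = c("median_center", "quantile",
                                                 "zscore")) {
  stopifnot(inherits(ds, "lfq_dataset"))
  method <- match.arg(method)
  mat <- ds$mat
  obs_n <- rowSums(!is.na(mat))
  if (any(obs_n == 0)) {
    abort(paste0("sample(s) with no observed values: ",
                 paste(rownames(mat)[obs_n == 0], collapse = ", ")))
  }
  mat <- switch(method,
    median_center = {
      med <- apply(mat, 1, median, na.rm = TRUE)
      mat - med + median(med)
    },
    quantile = quantile_normalize(mat),
    zscore = {
      if (any(obs_n < 2)) {
        abort("zscore needs >= 2 observed values per sample")
      }
      m <- rowMeans(mat, na.rm = TRUE)
      s <- apply(mat, 1, sd, na.rm = TRUE)
      if (any(s == 0)) abort("zscore undefined for constant samples")
      (mat - m) / s
    })
  ds$mat <- mat
  add_step(ds, "normalize", list(method = method), nrow(mat))
}

quantile_normalize <- function(mat) {
  n <- nrow(mat)
  complete <- colSums(is.na(mat)) == 0
  if (any(complete)) {
    sub <- mat[, complete, drop = FALSE]
    ref <- rowMeans(apply(sub, 1, sort)) # m x n after apply; rows are ranks
  } else {
    len <- max(rowSums(!is.na(mat)))
    probs <- if (len == 1) 0.5 else (seq_len(len) - 1) / (len - 1)
    per_sample <- vapply(seq_len(n), function(i) {
      quantile(mat[i, ], probs = probs, na.rm = TRUE, names = FALSE, type = 7)
    }, numeric(len))
    ref <- rowMeans(per_sample)
  }
  for (i in seq_len(n)) {
    obs <- which(!is.na(mat[i, ]))
    x <- mat[i, obs]
    k <- length(x)
    probs <- if (k == 1) 0.5 else (seq_len(k) - 1) / (k - 1)
    target <- quantile(ref, probs = probs, names = FALSE, type = 7)
    assigned <- numeric(k)
    assigned[order(x)] <- target
    # tied input values share the mean of their ranks' reference values
    assigned <- stats::ave(assigned, x, FUN = mean)
    mat[i, obs] <- assigned
  }
  mat
}

#' Impute missing intensities
#'
#' Fills every missing cell; observed cells are never altered. Methods:
#'
#' * `mean` / `median`: the per-protein statistic over observed samples.
#' * `knn`: the per-protein mean of the `k` nearest samples (Euclidean
#'   distance over mutually observed proteins, scaled by the number shared;
#'   ties broken by sample order; neighbours must have the protein observed
#'   and share at least one observed protein, otherwise the per-protein mean
#'   is used as fallback).
#' * `tree_iterative`: iterative chained prediction with random-forest
#'   regressions (one model per incomplete protein, all other proteins as
#'   features), in the spirit of missForest. Missing cells are initialised
#'   with per-protein means, proteins visited in descending-missingness
#'   order, and iteration stops at `max_iter` rounds or when the relative
#'   change of the imputed cells drops below `tol`.
#'
#' @param ds An [lfq_dataset]; every protein needs at least one observed
#'   value (use [filter_completeness()]).
#' @param method One of `"mean"`, `"median"`, `"knn"`, `"tree_iterative"`.
#' @param seed Integer seed (required for `tree_iterative`; recorded in the
#'   log for all methods so replays are exact).
#' @param k Neighbour count for `knn`; must be `< n_samples`.
#' @param n_estimators Trees per forest for `tree_iterative`.
#' @param max_iter,tol Iteration cap and relative-change tolerance for
#'   `tree_iterative`.
#' @return The imputed dataset (no missing cells).
#' @export
impute_intensities <- function(ds, method = c("mean", "median", "knn",
                                              "tree_iterative"),
                               seed = 0L, k = 3L, n_estimators = 100L,
                               max_iter = 10L, tol = 1e-3) {
  stopifnot(inherits(ds, "lfq_dataset"))
  method <- match.arg(method)
  mat <- ds$mat
  all_missing <- colSums(!is.na(mat)) == 0
  if (any(all_missing)) {
    abort(paste0("protein(s) with no observed values cannot be imputed: ",
                 paste(colnames(mat)[all_missing], collapse = ", "),
                 " (apply filter_completeness first)"))
  }
  out <- switch(method,
    mean = fill_by_protein(mat, function(v) mean(v, na.rm = TRUE)),
    median = fill_by_protein(mat, function(v) median(v, na.rm = TRUE)),
    knn = impute_knn(mat, k),
    tree_iterative = impute_tree(mat, seed, n_estimators, max_iter, tol))
  ds$mat <- out
  add_step(ds, "impute",
           list(method = method, seed = seed, k = k,
                n_estimators = n_estimators, max_iter = max_iter, tol = tol),
           sum(is.na(mat)))
}

fill_by_protein <- function(mat, stat) {
  fill <- apply(mat, 2, stat)
  idx <- which(is.na(mat), arr.ind = TRUE)
  mat[idx] <- fill[idx[, 2]]
  mat
}

impute_knn <- function(mat, k) {
  n <- nrow(mat)
  if (k >= n) abort("knn imputation requires k < n_samples")
  obs <- !is.na(mat)
  # pairwise distances over mutually observed proteins, scaled by count
  dmat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- obs[i, ] & obs[j, ]
      ns <- sum(shared)
      if (ns > 0) {
        dmat[i, j] <- sqrt(sum((mat[i, shared] - mat[j, shared])^2) / ns)
      }
    }
  }
  prot_mean <- colMeans(mat, na.rm = TRUE)
  out <- mat
  for (idx in which(!obs)) {
    i <- ((idx - 1) %% n) + 1
    p <- ((idx - 1) %/% n) + 1
    cand <- which(obs[, p] & !is.na(dmat[i, ]))
    if (length(cand) == 0) {
      out[i, p] <- prot_mean[p]
      next
    }
    ord <- cand[order(dmat[i, cand], cand)] # ties broken by sample order
    nb <- head(ord, k)
    out[i, p] <- mean(mat[nb, p])
  }
  out
}

impute_tree <- function(mat, seed, n_estimators, max_iter, tol) {
  obs <- !is.na(mat)
  miss_per_col <- colSums(!obs)
  cols <- order(miss_per_col, decreasing = TRUE)
  cols <- cols[miss_per_col[cols] > 0]
  if (length(cols) == 0) return(mat)

  x <- fill_by_protein(mat, function(v) mean(v, na.rm = TRUE))
  miss_idx <- which(!obs)
  for (iter in seq_len(max_iter)) {
    prev <- x[miss_idx]
    for (j in cols) {
      oi <- obs[, j]
      if (sum(oi) < 2 || sd(mat[oi, j]) == 0) next # mean init stands
      feats <- x[, -j, drop = FALSE]
      fit <- ranger::ranger(
        x = feats[oi, , drop = FALSE], y = mat[oi, j],
        num.trees = n_estimators, num.threads = 1,
        # regression-forest default (as in missForest): mtry = p/3
        mtry = max(1L, floor(ncol(feats) / 3)),
        seed = (seed + 131L * iter + j) %% .Machine$integer.max)
      x[!oi, j] <- stats::predict(
        fit, data = feats[!oi, , drop = FALSE],
        num.threads = 1)$predictions
    }
    change <- sum((x[miss_idx] - prev)^2) / max(sum(prev^2), .Machine$double.eps)
    if (change < tol) break
  }
  x[obs] <- mat[obs]
  x
}

#' Enumerate preprocessing pipeline variants
#'
#' Runs the cross product of normalization and imputation choices on the same
#' dataset, returning one fully preprocessed dataset per combination, each
#' with its own complete provenance log. This is the mechanism behind
#' systematic method comparison: downstream analyses can be mapped over the
#' result.
#'
#' @param ds An [lfq_dataset], already filtered/log-transformed as desired.
#' @param normalizations Character vector of [normalize_intensities()]
#'   methods; `"none"` skips normalization.
#' @param imputations Character vector of [impute_intensities()] methods;
#'   `"none"` skips imputation.
#' @param seed Seed passed to stochastic imputation methods.
#' @param k,n_estimators Parameters forwarded to [impute_intensities()].
#' @return A named list of datasets, names `"<normalization>+<imputation>"`.
#' @export
preprocess_variants <- function(ds, normalizations = "median_center",
                                imputations = c("mean", "knn",
                                                "tree_iterative"),
                                seed = 0L, k = 3L, n_estimators = 100L) {
  combos <- tidyr::expand_grid(normalization = normalizations,
                               imputation = imputations)
  out <- purrr::pmap(combos, function(normalization, imputation) {
    d <- ds
    if (normalization != "none") {
      d <- normalize_intensities(d, normalization)
    }
    if (imputation != "none") {
      d <- impute_intensities(d, imputation, seed = seed, k = k,
                              n_estimators = n_estimators)
    }
    d
  })
  names(out) <- paste(combos$normalization, combos$imputation, sep = "+")
  out
}
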