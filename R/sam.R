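#' Significance analysis of microarrays (two-class, unpaired)
#'
#' Permutation-based differential-expression test with a variance-stabilized
#' statistic. Per protein, the relative difference is
#' `d = (mean(group1) - mean(group2)) / (s + s0)` where `s` is the pooled
#' standard error and `s0` a small "fudge factor" that damps the otherwise
#' inflated d of low-variance proteins. In `auto` mode `s0` is selected among
#' the 0th, 5th, ..., 100th percentiles of the `s` distribution as the value
#' minimizing the coefficient of variation of the median absolute deviation
#' of `d` across windows of `s` quantiles.
#'
#' The null distribution comes from relabelling: all distinct assignments of
#' samples to the two groups are enumerated when their number is at most
#' `n_perm`, otherwise `n_perm` assignments are drawn uniformly using `seed`.
#' The expected order statistics `d_bar` are the per-rank means of the
#' permuted, sorted d-scores. Calling at threshold `delta` follows the
#' classic outward scan: starting from the origin of the expected scores and
#' moving up (down), the first rank where `d_(i) - d_bar_(i) >= delta`
#' (`<= -delta`) fixes the upper (lower) cut, and every protein beyond a cut
#' is called. The FDR at `delta` is
#' `pi0 * median(false calls per permutation) / n_called`, where false calls
#' count permuted d-scores outside the data-derived cut thresholds and `pi0`
#' is estimated from the fraction of observed d inside the permutation null's
#' interquartile band. Per-protein permutation p-values use the +1
#' correction, so they are never exactly zero.
#'
#' Proteins with fewer than two observed values in either group are excluded
#' (reported with `NA` scores); the remaining submatrix must be complete —
#' impute first — so that the permutation null is exact.
#'
#' @inheritParams de_ttest
#' @param n_perm Maximum number of permutations (>= 1).
#' @param delta Calling threshold (>= 0), or `NULL` to pick the smallest
#'   delta in the delta table with FDR <= 0.05.
#' @param s0_mode `"auto"` (percentile search) or `"fixed"`.
#' @param s0_value The fudge factor when `s0_mode = "fixed"`.
#' @param seed Integer seed for sampled permutations.
#' @return A `sam_result`: a tibble with `protein_id`, `d`, `s`, `rank`,
#'   `d_bar` (expected order statistic at that rank), `perm_p`, `called`,
#'   `status`; attributes `s0`, `delta`, `pi0`, `n_perm_used`, `exhaustive`
#'   and `delta_table` (tibble of delta, n_called, median_false_called, fdr).
#' @export
sam <- function(ds, group_column, group1, group2, n_perm = 1000L,
                delta = NULL, s0_mode = c("auto", "fixed"), s0_value = NULL,
                seed = 0L) {
  stopifnot(inherits(ds, "lfq_dataset"))
  s0_mode <- match.arg(s0_mode)
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (identical(group1, group2)) abort("group1 and group2 must differ")
  g <- group_values(ds, group_column)
  i1 <- which(g == group1); i2 <- which(g == group2)
  if (length(i1) < 2 || length(i2) < 2) {
    abort("SAM needs at least 2 samples per group")
  }
  m <- ds$mat[c(i1, i2), , drop = FALSE]
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2

  obs1 <- colSums(!is.na(m[seq_len(n1), , drop = FALSE]))
  obs2 <- colSums(!is.na(m[n1 + seq_len(n2), , drop = FALSE]))
  tested <- obs1 >= 2 & obs2 >= 2
  if (anyNA(m[, tested, drop = FALSE])) {
    abort(paste0("SAM requires a complete matrix over the tested proteins; ",
                 "impute missing values first"))
  }
  mt <- m[, tested, drop = FALSE]
  p <- ncol(mt)
  if (p < 2) abort("fewer than 2 testable proteins")

  base <- sam_numerator(mt, seq_len(n1), n1 + seq_len(n2))
  s0 <- switch(s0_mode,
    fixed = {
      if (is.null(s0_value) || s0_value < 0) {
        abort("s0_mode = 'fixed' needs a non-negative s0_value")
      }
      s0_value
    },
    auto = tune_s0(base$num, base$s))
  d <- base$num / (base$s + s0)

  # permutation null: exhaustive when feasible, else seeded uniform draws
  total <- choose(n, n1)
  exhaustive <- total <= n_perm
  if (exhaustive) {
    combs <- combn(n, n1)
  } else {
    combs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) sort(sample.int(n, n1)),
             integer(n1))
    })
    if (n1 == 1) combs <- matrix(combs, nrow = 1)
  }
  B <- ncol(combs)
  D <- vapply(seq_len(B), function(b) {
    ii1 <- combs[, b]
    x <- sam_numerator(mt, ii1, setdiff(seq_len(n), ii1))
    x$num / (x$s + s0)
  }, numeric(p))
  if (p == 1) D <- matrix(D, nrow = 1)

  ord <- order(d)
  d_sorted <- d[ord]
  D_sorted <- apply(D, 2, sort)
  if (p == 1) D_sorted <- matrix(D_sorted, nrow = 1)
  d_bar <- rowMeans(D_sorted)
  dev <- d_sorted - d_bar

  q <- quantile(D, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, mean(d >= q[1] & d <= q[2]) / 0.5)

  delta_grid <- sort(unique(c(0, abs(dev))))
  delta_table <- dplyr::bind_rows(lapply(delta_grid, function(dl) {
    sam_fdr_at(dl, d_sorted, d_bar, D, pi0)
  }))

  if (is.null(delta)) {
    ok <- delta_table$fdr <= 0.05 & delta_table$n_called > 0
    delta <- if (any(ok)) min(delta_table$delta[ok]) else
      max(delta_table$delta)
  }
  if (delta < 0) abort("delta must be >= 0")
  called_rank <- sam_cuts(delta, d_sorted, d_bar)$called

  perm_p <- vapply(seq_len(p), function(i) {
    (1 + sum(abs(D[i, ]) >= abs(d[i]))) / (1 + B)
  }, numeric(1))

  res <- tibble(protein_id = colnames(ds$mat),
                d = NA_real_, s = NA_real_, rank = NA_integer_,
                d_bar = NA_real_, perm_p = NA_real_, called = FALSE,
                status = "skipped_low_n")
  ti <- which(tested)
  res$d[ti] <- d
  res$s[ti] <- base$s
  rnk <- integer(p); rnk[ord] <- seq_len(p)
  res$rank[ti] <- rnk
  res$d_bar[ti] <- d_bar[rnk]
  res$perm_p[ti] <- perm_p
  res$called[ti] <- called_rank[rnk]
  res$status[ti] <- "ok"

  structure(res, class = c("sam_result", class(tibble())),
            s0 = s0, s0_mode = s0_mode, delta = delta, pi0 = pi0,
            n_perm_used = B, exhaustive = exhaustive, seed = seed,
            delta_table = delta_table,
            details = list(group_column = group_column, group1 = group1,
                           group2 = group2))
}

# numerator (mean difference) and pooled standard error per protein
sam_numerator <- function(m, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- colMeans(m[i1, , drop = FALSE])
  m2 <- colMeans(m[i2, , drop = FALSE])
  ss1 <- colSums(sweep(m[i1, , drop = FALSE], 2, m1)^2)
  ss2 <- colSums(sweep(m[i2, , drop = FALSE], 2, m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(num = m1 - m2, s = s)
}

# choose s0 among percentiles of s, minimizing the coefficient of variation
# of mad(d) across windows of s quantiles
tune_s0 <- function(num, s) {
  cand <- unique(quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  nw <- max(2L, min(10L, floor(length(s) / 5)))
  if (length(s) < 2 * nw) return(unname(stats::median(s)))
  breaks <- unique(quantile(s, probs = seq(0, 1, length.out = nw + 1),
                            names = FALSE))
  if (length(breaks) < 3) return(unname(stats::median(s)))
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(alpha) {
    dd <- num / (s + alpha)
    mads <- tapply(dd, win, stats::mad)
    mu <- mean(mads)
    if (!is.finite(mu) || mu == 0) return(Inf)
    stats::sd(mads) / mu
  }, numeric(1))
  cand[which.min(cv)] # which.min takes the first (smallest) on ties
}

# Tusher-style calling: starting at the origin of the expected scores and
# moving outward, the first rank whose deviation from the expected order
# statistic exceeds delta sets the cut; every protein beyond it is called.
# The outward scan (rather than a bare |d_(i) - d_bar_(i)| >= delta over all
# ranks) is what makes the degenerate all-null case call nothing: there the
# deviations exceed delta only on the wrong side of the origin.
sam_cuts <- function(delta, d_sorted, d_bar) {
  p <- length(d_sorted)
  dev <- d_sorted - d_bar
  called <- logical(p)
  cut_up <- Inf
  up_start <- match(TRUE, d_bar >= 0)
  if (!is.na(up_start)) {
    hit <- which(dev[up_start:p] >= delta)
    if (length(hit) > 0) {
      i <- up_start + hit[1] - 1L
      cut_up <- d_sorted[i]
      called[i:p] <- TRUE
    }
  }
  cut_low <- -Inf
  dn_idx <- which(d_bar <= 0)
  if (length(dn_idx) > 0) {
    dn_end <- max(dn_idx)
    hit <- which(dev[dn_end:1] <= -delta)
    if (length(hit) > 0) {
      i <- dn_end - hit[1] + 1L
      cut_low <- d_sorted[i]
      called[1:i] <- TRUE
    }
  }
  list(cut_up = cut_up, cut_low = cut_low, called = called)
}

sam_fdr_at <- function(delta, d_sorted, d_bar, D, pi0) {
  cuts <- sam_cuts(delta, d_sorted, d_bar)
  n_called <- sum(cuts$called)
  false_b <- vapply(seq_len(ncol(D)), function(b) {
    sum(D[, b] >= cuts$cut_up) + sum(D[, b] <= cuts$cut_low)
  }, numeric(1))
  med_false <- stats::median(false_b)
  fdr <- if (n_called == 0) 0 else min(1, pi0 * med_false / n_called)
  tibble(delta = delta, n_called = n_called,
         median_false_called = med_false, fdr = fdr)
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(
    "<sam_result> s0 = %.4g (%s), delta = %.4g, pi0 = %.3f, %d perms%s\n",
    attr(x, "s0"), attr(x, "s0_mode"), attr(x, "delta"), attr(x, "pi0"),
    attr(x, "n_perm_used"),
    if (attr(x, "exhaustive")) " (exhaustive)" else ""))
  cat("  called:", sum(x$called), "of", sum(x$status == "ok"), "tested\n")
  NextMethod()
}

#' @rdname sam
#' @param x A `sam_result`.
#' @param ... Unused.
#' @method glance sam_result
#' @export
glance.sam_result <- function(x, ...) {
  tibble(s0 = attr(x, "s0"), delta = attr(x, "delta"), pi0 = attr(x, "pi0"),
         n_perm = attr(x, "n_perm_used"), exhaustive = attr(x, "exhaustive"),
         n_called = sum(x$called), n_tested = sum(x$status == "ok"))
}

#' @rdname sam
#' @method tidy sam_result
#' @export
tidy.sam_result <- function(x, ...) as_tibble(x)

#' The delta/FDR table of a SAM fit
#'
#' @param x A `sam_result`.
#' @return Tibble with columns `delta`, `n_called`, `median_false_called`,
#'   `fdr`.
#' @export
sam_delta_table <- function(x) {
  stopifnot(inherits(x, "sam_result"))
  attr(x, "delta_table")
}
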