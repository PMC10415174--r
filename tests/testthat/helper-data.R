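# Build a dataset directly from a samples x proteins matrix (bypasses the
# non-negativity check of raw_protein_table, so normalized/log-scale toys
# with negative values are allowed).
make_ds <- function(mat, group = NULL, ..., contaminant = NULL) {
  storage.mode(mat) <- "double"
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("S%02d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("P%03d", seq_len(ncol(mat)))
  }
  md <- tibble::tibble(sample = rownames(mat))
  if (!is.null(group)) md$group <- group
  extra <- list(...)
  for (nm in names(extra)) md[[nm]] <- extra[[nm]]
  if (is.null(contaminant)) contaminant <- rep(FALSE, ncol(mat))
  lfqstats:::new_lfq_dataset(
    mat, md, "sample",
    annotations = tibble::tibble(protein_id = colnames(mat)),
    contaminant = stats::setNames(contaminant, colnames(mat)))
}

# A small dataset via the public path: fixture file -> loader -> dataset.
fixture_dataset <- function(n_proteins = 8, n_samples = 6, seed = 42,
                            dialect = "maxquant") {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  man <- make_fixture_file(dialect, n_proteins, n_samples, seed, f)
  tab <- flag_contaminants(load_table(f, dialect))
  md <- tibble::tibble(
    sample = man$sample_names,
    group = rep(c("A", "B"), length.out = n_samples))
  create_dataset(tab, md, "sample")
}

# Independent brute-force Benjamini-Hochberg step-up.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) min(ps[i:m] * m / (i:m)), numeric(1))
  q <- numeric(m)
  q[o] <- pmin(qs, 1)
  q
}

# Independent exhaustive SAM oracle for complete two-group matrices.
sam_oracle <- function(mat, i1, i2, s0, delta) {
  d_of <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    vapply(seq_len(ncol(mat)), function(p) {
      x1 <- mat[a, p]; x2 <- mat[b, p]
      s <- sqrt((1 / n1 + 1 / n2) *
                  (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) /
                  (n1 + n2 - 2))
      (mean(x1) - mean(x2)) / (s + s0)
    }, numeric(1))
  }
  n <- length(i1) + length(i2)
  pool <- c(i1, i2)
  combs <- utils::combn(n, length(i1))
  d <- d_of(i1, i2)
  D <- apply(combs, 2, function(cc) d_of(pool[cc], pool[-cc]))
  d_sorted <- sort(d)
  d_bar <- rowMeans(apply(D, 2, sort))
  dev <- d_sorted - d_bar
  # outward scan from the origin of the expected scores
  np <- length(d_sorted)
  called <- logical(np)
  cut_up <- Inf
  ups <- which(d_bar >= 0 & dev >= delta)
  ups <- ups[ups >= match(TRUE, d_bar >= 0)]
  if (length(ups) > 0) {
    cut_up <- d_sorted[min(ups)]
    called[min(ups):np] <- TRUE
  }
  cut_low <- -Inf
  dns <- which(d_bar <= 0 & dev <= -delta)
  if (length(dns) > 0) {
    cut_low <- d_sorted[max(dns)]
    called[1:max(dns)] <- TRUE
  }
  n_called <- sum(called)
  false_b <- apply(D, 2, function(col) {
    sum(col >= cut_up) + sum(col <= cut_low)
  })
  qq <- stats::quantile(D, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, mean(d >= qq[1] & d <= qq[2]) / 0.5)
  perm_p <- vapply(seq_along(d), function(i) {
    (1 + sum(abs(D[i, ]) >= abs(d[i]))) / (1 + ncol(D))
  }, numeric(1))
  list(d = d, d_bar = d_bar, n_called = n_called,
       median_false = stats::median(false_b), pi0 = pi0,
       fdr = if (n_called == 0) 0 else
         min(1, pi0 * stats::median(false_b) / n_called),
       perm_p = perm_p)
}
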