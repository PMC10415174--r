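new_de_result <- function(df, test, details = list()) {
  structure(df, class = c("de_result", class(tibble())),
            test = test, details = details)
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> test:", attr(x, "test"), "-",
      sum(x$status == "ok"), "tested /", sum(x$status == "skipped_low_n"),
      "skipped\n")
  NextMethod()
}

#' @rdname de_ttest
#' @param x A `de_result`.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble(test = attr(x, "test"), n_proteins = nrow(x),
         n_tested = sum(x$status == "ok"),
         n_skipped = sum(x$status == "skipped_low_n"),
         n_q05 = sum(x$q < 0.05, na.rm = TRUE))
}

#' @rdname de_ttest
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

group_values <- function(ds, group_column) {
  if (!group_column %in% names(ds$metadata)) {
    abort(paste0("metadata has no column '", group_column, "'"))
  }
  as.character(ds$metadata[[group_column]])
}

#' Per-protein two-sample t-test
#'
#' Runs a two-sided t-test (Welch by default, pooled-variance when
#' `equal_var = TRUE`) on the observed values of each protein, comparing two
#' groups from a metadata column. Intended for log2-scale intensities, so the
#' effect `log2_fc = mean(group1) - mean(group2)` is a log2 fold change.
#' Proteins with fewer than `min_obs` observed values in either group — or
#' with zero variance in both groups, where the statistic is undefined — are
#' reported with `status = "skipped_low_n"` and an undefined p. q-values are
#' Benjamini-Hochberg over the tested proteins only.
#'
#' @param ds An [lfq_dataset] (log2-transformed).
#' @param group_column Metadata column holding the group labels.
#' @param group1,group2 The two labels to compare.
#' @param equal_var Pooled-variance t-test instead of Welch.
#' @param min_obs Minimum observed values per group (>= 2).
#' @return A `de_result` tibble: `protein_id`, `log2_fc`, `statistic`, `p`,
#'   `q`, `n1`, `n2`, `status`.
#' @export
de_ttest <- function(ds, group_column, group1, group2, equal_var = FALSE,
                     min_obs = 2L) {
  stopifnot(inherits(ds, "lfq_dataset"), min_obs >= 2)
  g <- group_values(ds, group_column)
  for (lab in c(group1, group2)) {
    if (!lab %in% g) abort(paste0("no samples with ", group_column, " == '",
                                  lab, "'"))
  }
  i1 <- which(g == group1)
  i2 <- which(g == group2)

  rows <- purrr::map(seq_len(ncol(ds$mat)), function(p) {
    x1 <- ds$mat[i1, p]; x1 <- x1[!is.na(x1)]
    x2 <- ds$mat[i2, p]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    fc <- if (n1 >= 1 && n2 >= 1) mean(x1) - mean(x2) else NA_real_
    if (n1 < min_obs || n2 < min_obs) {
      return(tibble(log2_fc = fc, statistic = NA_real_, p = NA_real_,
                    n1 = n1, n2 = n2, status = "skipped_low_n"))
    }
    w <- welch_t(x1, x2, equal_var)
    if (is.na(w$t)) {
      return(tibble(log2_fc = fc, statistic = NA_real_, p = NA_real_,
                    n1 = n1, n2 = n2, status = "skipped_low_n"))
    }
    tibble(log2_fc = fc, statistic = w$t, p = w$p, n1 = n1, n2 = n2,
           status = "ok")
  })
  res <- dplyr::bind_cols(tibble(protein_id = colnames(ds$mat)),
                          dplyr::bind_rows(rows))
  res$q <- adjust_bh(res$p)
  res <- res[, c("protein_id", "log2_fc", "statistic", "p", "q",
                 "n1", "n2", "status")]
  new_de_result(res, test = if (equal_var) "ttest" else "welch_ttest",
                details = list(group_column = group_column,
                               group1 = group1, group2 = group2,
                               equal_var = equal_var, min_obs = min_obs))
}

# closed-form two-sample t; returns NA statistic when the standard error is 0
welch_t <- function(x1, x2, equal_var) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (!is.finite(se) || se == 0) return(list(t = NA_real_, p = NA_real_))
  t <- (mean(x1) - mean(x2)) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Per-protein one-way ANOVA
#'
#' Classic (equal-variance) one-way F-test across all levels of a metadata
#' column, on observed values. Groups with fewer than `min_obs` observed
#' values are excluded per protein; proteins left with fewer than two groups,
#' or with zero within-group variance, are skipped. With exactly two groups
#' the F statistic equals the square of the pooled-variance t statistic.
#'
#' @inheritParams de_ttest
#' @return A `de_result` tibble; `log2_fc` is undefined (multi-group), `n1`
#'   holds the total observed count and `n2` the number of groups used.
#' @export
de_anova <- function(ds, group_column, min_obs = 2L) {
  stopifnot(inherits(ds, "lfq_dataset"))
  g <- group_values(ds, group_column)
  if (length(unique(g)) < 2) {
    abort(paste0("column '", group_column, "' has fewer than 2 groups"))
  }
  rows <- purrr::map(seq_len(ncol(ds$mat)), function(p) {
    ok <- !is.na(ds$mat[, p])
    y <- ds$mat[ok, p]; gg <- g[ok]
    counts <- table(gg)
    use <- gg %in% names(counts)[counts >= min_obs]
    y <- y[use]; gg <- gg[use]
    n_groups <- length(unique(gg))
    skipped <- tibble(log2_fc = NA_real_, statistic = NA_real_, p = NA_real_,
                      n1 = length(y), n2 = n_groups, status = "skipped_low_n")
    if (n_groups < 2) return(skipped)
    fit <- tryCatch(
      stats::oneway.test(y ~ factor(gg), var.equal = TRUE),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$statistic)) return(skipped)
    tibble(log2_fc = NA_real_, statistic = unname(fit$statistic),
           p = unname(fit$p.value), n1 = length(y), n2 = n_groups,
           status = "ok")
  })
  res <- dplyr::bind_cols(tibble(protein_id = colnames(ds$mat)),
                          dplyr::bind_rows(rows))
  if (all(res$status == "skipped_low_n")) {
    warning("every protein was skipped; no testable groups", call. = FALSE)
  }
  res$q <- adjust_bh(res$p)
  res <- res[, c("protein_id", "log2_fc", "statistic", "p", "q",
                 "n1", "n2", "status")]
  new_de_result(res, "anova",
                list(group_column = group_column, min_obs = min_obs))
}

#' Per-protein ANCOVA (group effect adjusted for covariates)
#'
#' Least-squares fit of intensity on group indicators plus numeric
#' covariates; the p-value comes from the partial F-test of the full model
#' against the covariate-only model, i.e. it asks whether the group labels
#' explain variance beyond the covariates. Proteins whose observed design is
#' rank-deficient (e.g. collinear covariates) are skipped.
#'
#' @inheritParams de_ttest
#' @param covariates Character vector of numeric metadata columns.
#' @return A `de_result` tibble; `statistic` is the partial F.
#' @export
de_ancova <- function(ds, group_column, covariates, min_obs = 2L) {
  stopifnot(inherits(ds, "lfq_dataset"), length(covariates) >= 1)
  g <- group_values(ds, group_column)
  for (cv in covariates) {
    if (!cv %in% names(ds$metadata)) {
      abort(paste0("covariate column missing: ", cv))
    }
    if (!is.numeric(ds$metadata[[cv]])) {
      abort(paste0("covariate must be numeric: ", cv))
    }
  }
  covs <- as.data.frame(ds$metadata[, covariates, drop = FALSE])

  rows <- purrr::map(seq_len(ncol(ds$mat)), function(p) {
    ok <- !is.na(ds$mat[, p]) & !Reduce(`|`, lapply(covs, is.na))
    y <- ds$mat[ok, p]; gg <- g[ok]; cc <- covs[ok, , drop = FALSE]
    counts <- table(gg)
    skipped <- tibble(log2_fc = NA_real_, statistic = NA_real_, p = NA_real_,
                      n1 = length(y), n2 = length(unique(gg)),
                      status = "skipped_low_n")
    if (length(unique(gg)) < 2 || any(counts < min_obs)) return(skipped)
    dat <- data.frame(.y = y, .group = factor(gg), cc)
    full <- stats::model.matrix(
      stats::reformulate(c(".group", covariates)), dat)
    if (qr(full)$rank < ncol(full) ||
        nrow(dat) <= ncol(full)) {
      return(skipped)
    }
    fit0 <- stats::lm(stats::reformulate(covariates, ".y"), data = dat)
    fit1 <- stats::lm(stats::reformulate(c(".group", covariates), ".y"),
                      data = dat)
    cmp <- stats::anova(fit0, fit1)
    fstat <- cmp$F[2]; pval <- cmp$`Pr(>F)`[2]
    if (!is.finite(fstat)) return(skipped)
    tibble(log2_fc = NA_real_, statistic = fstat, p = pval,
           n1 = length(y), n2 = length(unique(gg)), status = "ok")
  })
  res <- dplyr::bind_cols(tibble(protein_id = colnames(ds$mat)),
                          dplyr::bind_rows(rows))
  res$q <- adjust_bh(res$p)
  res <- res[, c("protein_id", "log2_fc", "statistic", "p", "q",
                 "n1", "n2", "status")]
  new_de_result(res, "ancova",
                list(group_column = group_column, covariates = covariates,
                     min_obs = min_obs))
}

#' Benjamini-Hochberg adjustment tolerating undefined entries
#'
#' Step-up false-discovery-rate adjustment over the defined p-values only
#' (`m` = number of defined entries); `NA`s stay `NA` and output order
#' matches input order.
#'
#' @param p Numeric vector of p-values; `NA` allowed.
#' @return Vector of q-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must be in [0, 1]")
  }
  q <- rep(NA_real_, length(p))
  def <- !is.na(p)
  q[def] <- stats::p.adjust(p[def], method = "BH")
  q
}

#' Write a result table to TSV
#'
#' Column order is stable and documented in each result's constructor.
#'
#' @param x A `de_result`, `sam_result` delta table, or any data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA")
  invisible(path)
}
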