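#' Spike-in simulation design
#'
#' Parameters of a two-group synthetic spike-in experiment on the log2 scale.
#' Background proteins have no group effect; spiked proteins are shifted by
#' `log2_effect` in group 2. Missingness is applied completely at random
#' (MCAR) first, then intensity-dependent dropout (MNAR): cells whose
#' noise-free underlying intensity lies below the `mnar_quantile` quantile of
#' all noise-free cell values become missing with probability `mnar_prob`.
#'
#' Defaults emulate a routine label-free experiment: protein means uniform
#' over 14-26 log2 units (the typical LFQ dynamic range), measurement noise
#' of 0.3 log2 units, and dropout concentrated in the lowest intensity
#' quartile.
#'
#' @param n_background,n_spiked Protein counts.
#' @param n_per_group Samples per group (two groups).
#' @param log2_effect Spike shift in group 2, log2 units.
#' @param protein_mean_range Range of base log2 abundances.
#' @param noise_sd Gaussian noise sd, log2 units (> 0).
#' @param mcar_fraction Fraction of cells missing completely at random.
#' @param mnar_quantile Intensity quantile below which MNAR applies.
#' @param mnar_prob Dropout probability for cells below the MNAR quantile.
#' @param seed Integer seed.
#' @return A `spikein_design` list.
#' @export
spikein_design <- function(n_background = 480L, n_spiked = 20L,
                           n_per_group = 5L, log2_effect = 1,
                           protein_mean_range = c(14, 26), noise_sd = 0.3,
                           mcar_fraction = 0, mnar_quantile = 0.25,
                           mnar_prob = 0, seed = 1L) {
  d <- list(n_background = as.integer(n_background),
            n_spiked = as.integer(n_spiked),
            n_per_group = as.integer(n_per_group),
            log2_effect = log2_effect,
            protein_mean_range = as.numeric(protein_mean_range),
            noise_sd = noise_sd, mcar_fraction = mcar_fraction,
            mnar_quantile = mnar_quantile, mnar_prob = mnar_prob,
            seed = as.integer(seed))
  validate_spikein_design(d)
  structure(d, class = "spikein_design")
}

validate_spikein_design <- function(d) {
  ok <- d$n_background >= 0 && d$n_spiked >= 0 &&
    d$n_background + d$n_spiked >= 1 && d$n_per_group >= 1 &&
    d$noise_sd > 0 && length(d$protein_mean_range) == 2 &&
    d$protein_mean_range[1] <= d$protein_mean_range[2] &&
    d$mcar_fraction >= 0 && d$mcar_fraction < 1 &&
    d$mnar_quantile >= 0 && d$mnar_quantile < 1 &&
    d$mnar_prob >= 0 && d$mnar_prob <= 1
  if (!ok) abort("invalid spike-in design")
  invisible(d)
}

#' Serialize / read a spike-in design as YAML
#'
#' @param design A [spikein_design()].
#' @param path YAML file path.
#' @return `read_spikein_design()` returns the design; `write_spikein_design`
#'   the path, invisibly.
#' @export
write_spikein_design <- function(design, path) {
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}

#' @rdname write_spikein_design
#' @export
read_spikein_design <- function(path) {
  do.call(spikein_design, yaml::read_yaml(path))
}

#' Generate a ground-truth spike-in dataset
#'
#' Draws a seeded synthetic two-group experiment per the design: per-protein
#' base log2 means uniform over `protein_mean_range`, a `log2_effect` shift
#' for spiked proteins in group 2, i.i.d. Gaussian noise, then MCAR and MNAR
#' missingness. The result is a ready-made [lfq_dataset] (metadata column
#' `group` with levels `A`/`B`; spiked proteins are shifted up in `B`) plus
#' the per-protein truth.
#'
#' @param design A [spikein_design()].
#' @return A list with `dataset` (an [lfq_dataset], matrix on log2 scale) and
#'   `truth` (tibble `protein_id`, `is_spiked`, `true_log2_fc`).
#' @export
generate_spikein <- function(design) {
  validate_spikein_design(design)
  np <- design$n_background + design$n_spiked
  ns <- 2L * design$n_per_group
  with_seed(design$seed, {
    protein_ids <- sprintf("PROT%04d", seq_len(np))
    is_spiked <- c(rep(TRUE, design$n_spiked),
                   rep(FALSE, design$n_background))
    base <- stats::runif(np, design$protein_mean_range[1],
                         design$protein_mean_range[2])
    group <- rep(c("A", "B"), each = design$n_per_group)
    effect <- outer(group == "B", is_spiked) * design$log2_effect
    clean <- matrix(base, ns, np, byrow = TRUE) + effect
    noisy <- clean + matrix(stats::rnorm(ns * np, sd = design$noise_sd),
                            ns, np)
    miss <- matrix(stats::runif(ns * np) < design$mcar_fraction, ns, np)
    if (design$mnar_prob > 0) {
      cut <- quantile(clean, design$mnar_quantile, names = FALSE)
      low <- clean < cut
      miss <- miss | (low & matrix(stats::runif(ns * np) < design$mnar_prob,
                                   ns, np))
    }
    noisy[miss] <- NA_real_
    sample_ids <- sprintf("%s%02d", group, rep(seq_len(design$n_per_group),
                                               times = 2))
    dimnames(noisy) <- list(sample_ids, protein_ids)
    ds <- new_lfq_dataset(
      noisy,
      metadata = tibble(sample = sample_ids, group = group),
      sample_col = "sample",
      annotations = tibble(protein_id = protein_ids, is_spiked = is_spiked),
      contaminant = setNames(rep(FALSE, np), protein_ids))
    # convention: effects are group B vs group A, matching
    # de_ttest(ds, "group", "B", "A")
    truth <- tibble(protein_id = protein_ids, is_spiked = is_spiked,
                    true_log2_fc = ifelse(is_spiked, design$log2_effect, 0))
    list(dataset = ds, truth = truth)
  })
}

#' Rank-based ROC AUC of a differential-expression result
#'
#' The probability that a randomly chosen spiked protein outranks a randomly
#' chosen background protein under the given score (ties count one half) —
#' the Mann-Whitney form of the area under the ROC curve. Skipped proteins
#' receive the minimum score. The AUC is invariant to strictly monotone
#' transforms of the score.
#'
#' @param de A `de_result` (or data frame with `protein_id`, `p`,
#'   `statistic`, `status`).
#' @param truth Truth tibble from [generate_spikein()].
#' @param score `"neg_log_p"` (default) or `"abs_statistic"`.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(de, truth, score = c("neg_log_p", "abs_statistic")) {
  score <- match.arg(score)
  joined <- dplyr::inner_join(as_tibble(de), truth, by = "protein_id")
  if (nrow(joined) == 0) abort("de and truth share no protein ids")
  lab <- joined$is_spiked
  if (all(lab) || !any(lab)) {
    abort("AUC undefined: truth must contain both spiked and background")
  }
  s <- switch(score,
    neg_log_p = -log10(pmax(joined$p, .Machine$double.xmin)),
    abs_statistic = abs(joined$statistic))
  s[joined$status == "skipped_low_n" | is.na(s)] <- -Inf
  r <- rank(s) # average ranks: ties count 1/2 in the Mann-Whitney identity
  n1 <- sum(lab); n0 <- sum(!lab)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Benchmark preprocessing pipelines on a spike-in design
#'
#' Generates one dataset from the design, then runs every combination of
#' normalization and imputation through completeness filtering, the chosen
#' test, and [evaluate_auc()]. All combinations see the identical input
#' (same seed), so differences in AUC are attributable to the preprocessing
#' choice. Failed combinations are kept as rows marked `failed`.
#'
#' @param design A [spikein_design()].
#' @param normalizations Character vector (see [normalize_intensities()];
#'   `"none"` skips).
#' @param imputations Character vector (see [impute_intensities()]; `"none"`
#'   skips, only valid without missingness).
#' @param test `"ttest"` or `"sam"`.
#' @param min_fraction Completeness gate applied before
#'   normalization/imputation.
#' @param score Passed to [evaluate_auc()].
#' @param n_perm,k,n_estimators Forwarded to the respective methods.
#' @return A tibble `(normalization, imputation, auc, n_called_at_q05,
#'   failed)`, sorted by descending AUC.
#' @export
compare_pipelines <- function(design, normalizations = "median_center",
                              imputations = c("mean", "median", "knn",
                                              "tree_iterative"),
                              test = c("ttest", "sam"), min_fraction = 0.5,
                              score = "neg_log_p", n_perm = 250L, k = 3L,
                              n_estimators = 100L) {
  test <- match.arg(test)
  stopifnot(length(normalizations) >= 1, length(imputations) >= 1)
  sim <- generate_spikein(design)
  base <- filter_completeness(sim$dataset, min_fraction)

  combos <- tidyr::expand_grid(normalization = normalizations,
                               imputation = imputations)
  rows <- purrr::pmap(combos, function(normalization, imputation) {
    out <- tryCatch({
      d <- base
      if (normalization != "none") d <- normalize_intensities(d, normalization)
      if (imputation != "none") {
        d <- impute_intensities(d, imputation, seed = design$seed, k = k,
                                n_estimators = n_estimators)
      }
      if (test == "ttest") {
        de <- de_ttest(d, "group", "B", "A")
        n05 <- sum(de$q < 0.05, na.rm = TRUE)
        auc <- evaluate_auc(de, sim$truth, score)
      } else {
        fit <- sam(d, "group", "B", "A", n_perm = n_perm,
                   seed = design$seed)
        n05 <- sum(fit$called, na.rm = TRUE)
        auc <- evaluate_auc(
          tibble(protein_id = fit$protein_id,
                 p = fit$perm_p, statistic = fit$d, status = fit$status),
          sim$truth,
          if (score == "neg_log_p") "neg_log_p" else "abs_statistic")
      }
      tibble(auc = auc, n_called_at_q05 = n05, failed = FALSE)
    }, error = function(e) {
      tibble(auc = NA_real_, n_called_at_q05 = NA_integer_, failed = TRUE)
    })
    dplyr::bind_cols(tibble(normalization = normalization,
                            imputation = imputation), out)
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$auc)), dplyr::desc(.data$auc))
}
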