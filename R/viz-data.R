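#' Volcano plot data
#'
#' Classifies each protein of a differential-expression result by effect-size
#' and significance thresholds: `up` when `log2_fc >= fc_cutoff` and
#' `-log10(p) >= -log10(alpha)`, `down` symmetrically, `skipped` for untested
#' proteins, `not_significant` otherwise. The y-axis uses the raw p-value by
#' default (`use_adjusted = TRUE` switches to the BH q); p-values of exactly
#' 0 are clamped to the smallest positive double and flagged in the `clamped`
#' column.
#'
#' @param de A `de_result` (see [de_ttest()]).
#' @param fc_cutoff Absolute log2 fold-change cutoff (>= 0).
#' @param alpha Significance cutoff in (0, 1).
#' @param use_adjusted Use q instead of raw p on the y axis.
#' @param label Optional character vector of protein ids to annotate.
#' @return A `volcano_data` tibble: `protein_id`, `x` (log2_fc), `y`
#'   (-log10 p or q), `class`, `clamped`, `label`.
#' @export
volcano_data <- function(de, fc_cutoff = 1, alpha = 0.05,
                         use_adjusted = FALSE, label = character()) {
  stopifnot(is.data.frame(de), nrow(de) > 0, fc_cutoff >= 0)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  pv <- if (use_adjusted) de$q else de$p
  clamped <- !is.na(pv) & pv == 0
  pv[clamped] <- .Machine$double.xmin
  y <- -log10(pv)
  ythr <- -log10(alpha)
  cls <- ifelse(de$status == "skipped_low_n", "skipped",
         ifelse(!is.na(y) & y >= ythr & de$log2_fc >= fc_cutoff, "up",
         ifelse(!is.na(y) & y >= ythr & de$log2_fc <= -fc_cutoff, "down",
                "not_significant")))
  out <- tibble(protein_id = de$protein_id, x = de$log2_fc, y = y,
                class = cls, clamped = clamped,
                label = ifelse(de$protein_id %in% label, de$protein_id, NA))
  out$y[out$class == "skipped"] <- NA_real_
  structure(out, class = c("volcano_data", class(tibble())),
            fc_cutoff = fc_cutoff, alpha = alpha,
            use_adjusted = use_adjusted)
}

#' Heatmap data with optional clustering
#'
#' Reorders the intensity matrix by hierarchical clustering of samples and/or
#' proteins; without clustering the input order is kept. The returned matrix
#' is a pure permutation of the input.
#'
#' @param ds An [lfq_dataset] with no missing values.
#' @param cluster_samples,cluster_proteins Cluster that axis?
#' @param metric,linkage Passed to [hcluster()].
#' @return A `heatmap_data` list: `matrix` (reordered), `sample_order`,
#'   `protein_order` (integer permutations of the input order),
#'   `sample_tree`, `protein_tree` ([hcluster()] results or `NULL`).
#' @export
heatmap_data <- function(ds, cluster_samples = TRUE, cluster_proteins = TRUE,
                         metric = "euclidean", linkage = "average") {
  stopifnot(inherits(ds, "lfq_dataset"))
  if (anyNA(ds$mat)) {
    abort("heatmap requires a complete matrix; impute missing values first")
  }
  s_tree <- p_tree <- NULL
  s_ord <- seq_len(nrow(ds$mat))
  p_ord <- seq_len(ncol(ds$mat))
  if (cluster_samples) {
    s_tree <- hcluster(ds$mat, "samples", metric, linkage)
    s_ord <- s_tree$leaf_order
  }
  if (cluster_proteins) {
    p_tree <- hcluster(ds$mat, "proteins", metric, linkage)
    p_ord <- p_tree$leaf_order
  }
  structure(list(matrix = ds$mat[s_ord, p_ord, drop = FALSE],
                 sample_order = s_ord, protein_order = p_ord,
                 sample_tree = s_tree, protein_tree = p_tree),
            class = "heatmap_data")
}

#' @export
print.heatmap_data <- function(x, ...) {
  cat("<heatmap_data> ", nrow(x$matrix), " x ", ncol(x$matrix),
      "; clustered: samples=", !is.null(x$sample_tree),
      ", proteins=", !is.null(x$protein_tree), "\n", sep = "")
  invisible(x)
}

#' Volcano ggplot
#'
#' @param object A [volcano_data()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot volcano_data
#' @export
autoplot.volcano_data <- function(object, ...) {
  ggplot2::ggplot(object[object$class != "skipped", ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "fc_cutoff"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(
      up = "#c0392b", down = "#2980b9", not_significant = "grey70")) +
    ggplot2::labs(
      x = "log2 fold change",
      y = if (attr(object, "use_adjusted")) "-log10 q" else "-log10 p") +
    ggplot2::theme_minimal()
}

#' PCA score ggplot
#'
#' @param object An `lfq_pca` from [pca_analysis()].
#' @param colour Metadata column mapped to colour (default first factor-like
#'   column other than the sample id, if any).
#' @param ... Unused.
#' @return A ggplot of the first two components.
#' @method autoplot lfq_pca
#' @export
autoplot.lfq_pca <- function(object, colour = NULL, ...) {
  df <- tidy.lfq_pca(object)
  evr <- object$explained_variance_ratio
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * evr[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * evr[2])) +
    ggplot2::theme_minimal()
  if (!is.null(colour) && colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
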