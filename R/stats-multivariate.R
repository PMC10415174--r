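#' Over-representation analysis of annotation terms
#'
#' Hypergeometric (upper-tail) enrichment of each annotation term in a
#' significant protein set against a background, the offline counterpart of a
#' gene-ontology enrichment. Terms are restricted to the background and to a
#' minimum size before testing; q-values are Benjamini-Hochberg across the
#' tested terms.
#'
#' @param significant Character vector of significant protein ids (must be a
#'   subset of `background`).
#' @param background Character vector: the tested universe.
#' @param annotation Term-to-protein mapping: a named list of protein-id
#'   vectors, or a two-column data frame `(term_id, protein_id)`.
#' @param min_term_size Smallest in-background term size tested.
#' @return An `ora_result` tibble: `term_id`, `n_term_background`,
#'   `n_term_hits`, `n_sig`, `n_background`, `p`, `q`, sorted by `p`.
#' @export
ora <- function(significant, background, annotation, min_term_size = 2L) {
  significant <- unique(significant)
  background <- unique(background)
  if (!all(significant %in% background)) {
    abort("significant proteins must be a subset of the background")
  }
  if (is.data.frame(annotation)) {
    annotation <- split(as.character(annotation[[2]]),
                        as.character(annotation[[1]]))
  }
  if (length(annotation) == 0) abort("annotation is empty")
  N <- length(background)
  n_sig <- length(significant)

  rows <- purrr::imap(annotation, function(prots, term) {
    inbg <- unique(prots[prots %in% background])
    K <- length(inbg)
    if (K < min_term_size) return(NULL)
    h <- sum(inbg %in% significant)
    tibble(term_id = term, n_term_background = K, n_term_hits = h,
           n_sig = n_sig, n_background = N,
           p = stats::phyper(h - 1, K, N - K, n_sig, lower.tail = FALSE))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble(term_id = character(), n_term_background = integer(),
                  n_term_hits = integer(), n_sig = integer(),
                  n_background = integer(), p = numeric(), q = numeric())
  } else {
    res$q <- adjust_bh(res$p)
    res <- dplyr::arrange(res, .data$p, .data$term_id)
  }
  structure(res, class = c("ora_result", class(tibble())))
}

#' Read a term-to-protein annotation file
#'
#' Accepts a two-column TSV `(term_id, protein_id)` (with or without a
#' header) or a GAF-like file (comment lines starting with `!`; protein id in
#' column 2, term id in column 5).
#'
#' @param path File path.
#' @return Tibble with columns `term_id`, `protein_id`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- max(lengths(fields))
  if (nf >= 15) { # GAF: DB, object id, symbol, qualifier, GO id, ...
    tibble(term_id = vapply(fields, `[[`, "", 5),
           protein_id = vapply(fields, `[[`, "", 2))
  } else {
    df <- tibble(term_id = vapply(fields, `[[`, "", 1),
                 protein_id = vapply(fields, `[[`, "", 2))
    if (nrow(df) > 0 && tolower(df$term_id[1]) %in%
          c("term", "term_id", "go", "go_id")) {
      df <- df[-1, ]
    }
    df
  }
}

#' Principal component analysis of a dataset
#'
#' Column-centered PCA of the samples x proteins matrix (no scaling).
#' Components are ordered by decreasing explained variance; as a sign
#' convention, each component is flipped so that its largest-magnitude
#' loading is positive.
#'
#' @param ds An [lfq_dataset] with no missing values (impute first).
#' @param n_components Number of components, at most
#'   `min(n_samples - 1, n_proteins)`.
#' @return An `lfq_pca` object: list with `scores` (samples x components),
#'   `loadings` (proteins x components, orthonormal),
#'   `explained_variance_ratio`, and the sample metadata.
#' @export
pca_analysis <- function(ds, n_components = 2L) {
  stopifnot(inherits(ds, "lfq_dataset"))
  if (anyNA(ds$mat)) {
    abort("PCA requires a complete matrix; impute missing values first")
  }
  max_nc <- min(nrow(ds$mat) - 1L, ncol(ds$mat))
  if (n_components > max_nc || n_components < 1) {
    abort(paste0("n_components must be in [1, ", max_nc, "]"))
  }
  pc <- stats::prcomp(ds$mat, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(n_components)
  loadings <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (j in keep) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr[keep],
                 metadata = ds$metadata, sample_col = ds$sample_col),
            class = "lfq_pca")
}

#' @export
print.lfq_pca <- function(x, ...) {
  cat("<lfq_pca> ", ncol(x$scores), " components; variance ratios: ",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname pca_analysis
#' @param x An `lfq_pca`.
#' @param ... Unused.
#' @return `tidy()` returns one row per sample with scores and metadata.
#' @method tidy lfq_pca
#' @export
tidy.lfq_pca <- function(x, ...) {
  sc <- as_tibble(x$scores, rownames = "sample_id")
  meta <- x$metadata
  names(meta)[names(meta) == x$sample_col] <- "sample_id"
  dplyr::left_join(sc, meta, by = "sample_id")
}

#' Agglomerative hierarchical clustering
#'
#' Clusters samples or proteins with Euclidean or correlation
#' (`1 - Pearson r`) distance and single/complete/average linkage. A thin,
#' contract-checked layer over [stats::hclust()].
#'
#' @param mat Numeric matrix (samples x proteins), no missing values.
#' @param axis Cluster `"samples"` (rows) or `"proteins"` (columns).
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `lfq_hclust` object: list with `merge_tree` (tibble of `step`,
#'   `left`, `right`, `height`; negative entries are leaves, positive entries
#'   earlier merges, as in [stats::hclust()]), `leaf_order`, `labels` and the
#'   underlying `hclust` object.
#' @export
hcluster <- function(mat, axis = c("samples", "proteins"),
                     metric = c("euclidean", "correlation"),
                     linkage = c("average", "complete", "single")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  x <- if (axis == "samples") mat else t(mat)
  if (nrow(x) < 2) abort("need at least 2 items to cluster")
  if (anyNA(x)) abort("clustering requires a complete matrix")
  d <- if (metric == "euclidean") {
    stats::dist(x)
  } else {
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      abort("correlation metric undefined for constant rows")
    }
    stats::as.dist(1 - stats::cor(t(x)))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(merge_tree = tibble(step = seq_len(nrow(hc$merge)),
                             left = hc$merge[, 1], right = hc$merge[, 2],
                             height = hc$height),
         leaf_order = hc$order,
         labels = rownames(x) %||% as.character(seq_len(nrow(x))),
         hclust = hc, axis = axis, metric = metric, linkage = linkage),
    class = "lfq_hclust")
}

#' @export
print.lfq_hclust <- function(x, ...) {
  cat("<lfq_hclust> ", length(x$labels), " ", x$axis, ", ", x$metric,
      " distance, ", x$linkage, " linkage\n", sep = "")
  invisible(x)
}
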