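#' Proteomics dataset with preprocessing provenance
#'
#' The central container of the package: a samples x proteins intensity
#' matrix joined to sample metadata, an immutable snapshot of the matrix at
#' creation, and an append-only log of every preprocessing step (name,
#' complete parameters including seeds, resulting shape, number of cells or
#' proteins affected). Replaying the log from the snapshot reproduces the
#' current matrix exactly, which is what makes an analysis reproducible.
#'
#' @name lfq_dataset
#' @seealso [create_dataset()], [reset_preprocessing()], [replay_log()],
#'   [subset_samples()], [summarize_dataset()]
NULL

new_lfq_dataset <- function(mat, metadata, sample_col, annotations,
                            contaminant, raw = mat,
                            raw_contaminant = contaminant, log = list()) {
  structure(
    list(mat = mat, metadata = metadata, sample_col = sample_col,
         annotations = annotations, contaminant = contaminant,
         raw = raw, raw_contaminant = raw_contaminant, log = log),
    class = "lfq_dataset")
}

#' Create a dataset from a raw protein table and sample metadata
#'
#' Joins the intensity matrix to the metadata by exact sample-name match
#' (surrounding whitespace stripped, no fuzzy matching) and transposes to the
#' statistical orientation: samples in rows, proteins in columns. Samples
#' present in the table but absent from the metadata are dropped with a
#' warning. The matrix at creation is stored as the immutable `raw` snapshot
#' and the preprocessing log starts empty.
#'
#' @param table A [raw_protein_table()].
#' @param metadata A data frame of per-sample metadata.
#' @param sample_column Name of the metadata column holding sample ids.
#' @return An object of class `lfq_dataset`.
#' @export
create_dataset <- function(table, metadata, sample_column = "sample") {
  stopifnot(inherits(table, "raw_protein_table"))
  metadata <- as_tibble(metadata)
  if (nrow(metadata) == 0) abort("metadata is empty")
  if (!sample_column %in% names(metadata)) {
    abort(paste0("metadata has no column '", sample_column, "'"))
  }
  ids <- trimws(as.character(metadata[[sample_column]]))
  if (any(!nzchar(ids))) abort("metadata contains empty sample ids")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated metadata sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  metadata[[sample_column]] <- ids

  tab_samples <- trimws(table$sample_names)
  keep <- tab_samples %in% ids
  if (!any(keep)) {
    abort(paste0("no overlap between table samples (",
                 paste(tab_samples, collapse = ", "), ") and metadata ids (",
                 paste(ids, collapse = ", "), ")"))
  }
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) absent from metadata: ",
            paste(tab_samples[!keep], collapse = ", "), call. = FALSE)
  }
  mat <- t(table$intensities[, keep, drop = FALSE])
  rownames(mat) <- tab_samples[keep]
  metadata <- metadata[match(rownames(mat), ids), , drop = FALSE]

  new_lfq_dataset(mat, metadata, sample_column, table$annotations,
                  setNames(table$contaminant, table$protein_ids))
}

n_samples <- function(ds) nrow(ds$mat)
n_proteins <- function(ds) ncol(ds$mat)

add_step <- function(ds, name, params, n_changed) {
  step <- list(name = name, params = params,
               shape_after = c(n_samples = nrow(ds$mat),
                               n_proteins = ncol(ds$mat)),
               n_removed_or_imputed = n_changed)
  ds$log <- c(ds$log, list(step))
  ds
}

#' @export
print.lfq_dataset <- function(x, ...) {
  cat("<lfq_dataset> ", nrow(x$mat), " samples x ", ncol(x$mat),
      " proteins\n", sep = "")
  nm <- sum(is.na(x$mat))
  cat("  missing cells: ", nm, sprintf(" (%.1f%%)", 100 * nm / length(x$mat)),
      "\n  preprocessing steps: ",
      if (length(x$log)) paste(vapply(x$log, `[[`, "", "name"),
                               collapse = " -> ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' @rdname lfq_dataset
#' @param x An `lfq_dataset`.
#' @param ... Unused.
#' @return `tidy()` returns one row per (sample, protein) cell with the
#'   intensity and the sample metadata joined on.
#' @method tidy lfq_dataset
#' @export
tidy.lfq_dataset <- function(x, ...) {
  long <- as_tibble(x$mat, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "protein_id",
                        values_to = "intensity")
  meta <- x$metadata
  names(meta)[names(meta) == x$sample_col] <- "sample_id"
  dplyr::left_join(long, meta, by = "sample_id")
}

#' @rdname lfq_dataset
#' @method glance lfq_dataset
#' @export
glance.lfq_dataset <- function(x, ...) {
  tibble(n_samples = nrow(x$mat), n_proteins = ncol(x$mat),
         missing_fraction = mean(is.na(x$mat)),
         n_contaminants = sum(x$contaminant),
         n_steps = length(x$log))
}

#' Summarize a dataset
#'
#' @param ds An [lfq_dataset].
#' @return A list with `n_samples`, `n_proteins`, `missing_fraction`
#'   (overall), `per_sample_missing` (tibble of per-sample missing
#'   fractions), and `n_contaminants` (currently flagged proteins).
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "lfq_dataset"))
  list(n_samples = nrow(ds$mat),
       n_proteins = ncol(ds$mat),
       missing_fraction = mean(is.na(ds$mat)),
       per_sample_missing = tibble(
         sample_id = rownames(ds$mat),
         missing_fraction = unname(rowMeans(is.na(ds$mat)))),
       n_contaminants = sum(ds$contaminant))
}

#' Reset preprocessing
#'
#' Restores the matrix (and contaminant flags) to the `raw` snapshot and
#' empties the log. Because the snapshot is re-based on [subset_samples()],
#' resetting undoes preprocessing but not subsetting.
#'
#' @param ds An [lfq_dataset].
#' @return The reset dataset.
#' @export
reset_preprocessing <- function(ds) {
  stopifnot(inherits(ds, "lfq_dataset"))
  ds$mat <- ds$raw
  ds$contaminant <- ds$raw_contaminant
  ds$log <- list()
  ds
}

#' Replay the preprocessing log
#'
#' Re-executes every logged step (subset steps are part of the snapshot and
#' are skipped) from the raw snapshot. With the same parameters and seeds the
#' result is bit-for-bit identical to the current matrix.
#'
#' @param ds An [lfq_dataset].
#' @param log Optional log to replay instead of `ds$log` (a list of steps as
#'   stored in the dataset).
#' @return A new `lfq_dataset` whose matrix equals the replayed state.
#' @export
replay_log <- function(ds, log = ds$log) {
  out <- reset_preprocessing(ds)
  for (step in log) {
    if (step$name == "subset") next
    out <- apply_step(out, step$name, step$params)
  }
  out
}

apply_step <- function(ds, name, params) {
  switch(name,
    remove_contaminants = remove_contaminants(ds),
    zero_to_missing = zero_to_missing(ds),
    filter_completeness = filter_completeness(ds, params$min_fraction),
    log2_transform = log2_transform(ds),
    normalize = normalize_intensities(ds, params$method),
    impute = impute_intensities(
      ds, params$method, seed = params$seed,
      k = params$k %||% 3L,
      n_estimators = params$n_estimators %||% 100L,
      max_iter = params$max_iter %||% 10L),
    abort(paste0("unknown preprocessing step in log: ", name))
  )
}

#' Subset samples
#'
#' Filters samples by a predicate over metadata columns (tidy evaluation) or
#' an explicit vector of sample ids. Proteins are unchanged. The raw snapshot
#' is re-based to the subset, so a later [reset_preprocessing()] keeps the
#' subsetting; a `subset` step is logged.
#'
#' @param ds An [lfq_dataset].
#' @param keep A predicate expression over metadata columns (e.g.
#'   `group == "A"`).
#' @param samples Alternatively, a character vector of sample ids.
#' @return The subsetted dataset.
#' @examples \dontrun{subset_samples(ds, group == "A")}
#' @export
subset_samples <- function(ds, keep = NULL, samples = NULL) {
  stopifnot(inherits(ds, "lfq_dataset"))
  if (!is.null(samples)) {
    idx <- rownames(ds$mat) %in% samples
    desc <- paste0("samples: ", paste(samples, collapse = ","))
  } else {
    expr <- rlang::enquo(keep)
    vals <- rlang::eval_tidy(expr, data = ds$metadata)
    if (!is.logical(vals) || length(vals) != nrow(ds$metadata)) {
      abort("subset predicate must evaluate to one logical per sample")
    }
    idx <- !is.na(vals) & vals
    desc <- rlang::as_label(expr)
  }
  if (!any(idx)) abort("subset would leave zero samples")
  ds$mat <- ds$mat[idx, , drop = FALSE]
  ds$metadata <- ds$metadata[idx, , drop = FALSE]
  ds$raw <- ds$raw[idx, , drop = FALSE]
  add_step(ds, "subset", list(predicate = desc), sum(!idx))
}

#' Serialize a dataset to a directory
#'
#' Writes the matrix, raw snapshot, metadata, annotations (TSV) and the
#' provenance log (JSON) as plain text. Numeric values are written with 17
#' significant digits so that [load_dataset()] restores them bit-for-bit.
#'
#' @param ds An [lfq_dataset].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "lfq_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_num_tsv(ds$mat, file.path(dir, "matrix.tsv"))
  write_num_tsv(ds$raw, file.path(dir, "raw.tsv"))
  readr::write_tsv(ds$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(ds$annotations, file.path(dir, "annotations.tsv"))
  jsonlite::write_json(
    list(sample_col = ds$sample_col,
         contaminant = as.list(setNames(as.logical(ds$contaminant),
                                        names(ds$contaminant))),
         raw_contaminant = as.list(setNames(as.logical(ds$raw_contaminant),
                                            names(ds$raw_contaminant))),
         log = ds$log),
    file.path(dir, "log.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

write_num_tsv <- function(mat, path) {
  header <- paste(c("sample_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            ifelse(is.na(mat[i, ]), "NA", sprintf("%.17g", mat[i, ]))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
}

read_num_tsv <- function(path) {
  df <- read_delim_chr(path, "\t")
  ids <- df[[1]]
  mat <- vapply(names(df)[-1], function(cn) {
    v <- df[[cn]]
    out <- rep(NA_real_, length(v))
    ok <- v != "NA"
    out[ok] <- as.numeric(v[ok])
    out
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L,
                                    dimnames = list(NULL, names(df)[-1]))
  rownames(mat) <- ids
  mat
}

#' Load a dataset saved by [save_dataset()]
#'
#' @param dir Directory written by [save_dataset()].
#' @return An [lfq_dataset].
#' @export
load_dataset <- function(dir) {
  mat <- read_num_tsv(file.path(dir, "matrix.tsv"))
  raw <- read_num_tsv(file.path(dir, "raw.tsv"))
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  ann <- readr::read_tsv(file.path(dir, "annotations.tsv"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  js <- jsonlite::read_json(file.path(dir, "log.json"))
  log <- lapply(js$log, function(s) {
    list(name = s$name, params = lapply(s$params, simplify_scalar),
         shape_after = unlist(s$shape_after),
         n_removed_or_imputed = s$n_removed_or_imputed)
  })
  new_lfq_dataset(
    mat, as_tibble(meta), js$sample_col, as_tibble(ann),
    contaminant = setNames(unlist(js$contaminant, use.names = FALSE),
                           colnames(mat)),
    raw = raw,
    raw_contaminant = setNames(unlist(js$raw_contaminant, use.names = FALSE),
                               colnames(raw)),
    log = log)
}

simplify_scalar <- function(x) {
  if (is.list(x)) unlist(x, use.names = FALSE) else x
}
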