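run_config_keys <- c("schema_version", "input", "dialect",
                     "intensity_preference", "metadata", "sample_column",
                     "contaminants", "preprocess", "analysis", "out", "seed",
                     "style")
preprocess_vocabulary <- c("remove_contaminants", "zero_to_missing",
                           "filter_completeness", "log2_transform",
                           "normalize", "impute")
analysis_vocabulary <- c("ttest", "welch_ttest", "anova", "ancova", "sam")

#' Read, validate and write run configurations
#'
#' A run configuration is a versioned YAML document describing one complete
#' analysis: input file and dialect, metadata, an ordered list of
#' preprocessing steps with their parameters, the statistical analysis, the
#' output directory and a global seed. Unknown keys and unknown step names
#' are errors, not warnings — a typo in an analysis config must not silently
#' change the analysis. A seed is required whenever a stochastic step
#' (tree-ensemble imputation, sampled SAM permutations) is configured.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (req in c("input", "metadata", "out")) {
    if (is.null(config[[req]])) abort(paste0("config field missing: ", req))
  }
  config$schema_version <- config$schema_version %||% 1L
  config$dialect <- config$dialect %||% "auto"
  config$sample_column <- config$sample_column %||% "sample"
  config$preprocess <- config$preprocess %||% list()
  stochastic <- FALSE
  for (i in seq_along(config$preprocess)) {
    st <- config$preprocess[[i]]
    if (is.null(st$step)) abort(paste0("preprocess entry ", i,
                                       " has no 'step' field"))
    if (!st$step %in% preprocess_vocabulary) {
      abort(paste0("unknown preprocessing step: '", st$step, "'"))
    }
    extra <- setdiff(names(st), c("step", "min_fraction", "method", "k",
                                  "n_estimators", "max_iter", "tol"))
    if (length(extra) > 0) {
      abort(paste0("unknown parameter(s) for step '", st$step, "': ",
                   paste(extra, collapse = ", ")))
    }
    if (st$step == "impute" && identical(st$method, "tree_iterative")) {
      stochastic <- TRUE
    }
  }
  if (!is.null(config$analysis)) {
    an <- config$analysis
    if (is.null(an$test) || !an$test %in% analysis_vocabulary) {
      abort(paste0("unknown analysis test '", an$test %||% "(none)",
                   "'; must be one of: ",
                   paste(analysis_vocabulary, collapse = ", ")))
    }
    if (is.null(an$group_column)) abort("analysis needs group_column")
    if (an$test == "sam") stochastic <- TRUE
  }
  if (stochastic && is.null(config$seed)) {
    abort("config must set a seed: a stochastic step is configured")
  }
  config$seed <- config$seed %||% 0L
  structure(config, class = "run_config")
}

log_msg <- function(level, msg, logfile = NULL) {
  line <- paste0("[", level, "] ", msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes a validated configuration end to end: import (with dialect
#' auto-detection if requested), contaminant flagging, dataset creation,
#' every configured preprocessing step, the configured statistical test, and
#' plot rendering. Writes, under `config$out`: the serialized dataset
#' (`dataset/`), `de_results.tsv` (or `sam_results.tsv` plus
#' `sam_delta_table.tsv`), `volcano.svg`/`volcano_data.tsv` for two-group
#' tests, `pca_scores.tsv` and `pca.svg` when the matrix is complete,
#' `provenance.json` (the preprocessing log), a `MANIFEST.json` noting the
#' completion state, and `run.log`. With an identical config and seed the
#' TSV and SVG outputs are byte-identical between runs.
#'
#' @param config A `run_config` (see [read_run_config()]) or path to one.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  cat("", file = logfile)
  manifest <- list(completed = character(), failed = NULL,
                   outputs = character())
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  tryCatch({
    log_msg("INFO", paste0("import: ", config$input, " (dialect ",
                           config$dialect, ")"), logfile)
    ds <- stage_import(config$input, config$dialect, config$metadata,
                       config$sample_column,
                       intensity_preference = config$intensity_preference,
                       contaminants = config$contaminants)
    manifest$completed <- c(manifest$completed, "import")

    for (st in config$preprocess) {
      log_msg("INFO", paste0("preprocess: ", st$step, " ",
                             jsonlite::toJSON(st, auto_unbox = TRUE)),
              logfile)
      ds <- apply_config_step(ds, st, config$seed)
    }
    dsdir <- file.path(out, "dataset")
    save_dataset(ds, dsdir)
    jsonlite::write_json(ds$log, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest$completed <- c(manifest$completed, "preprocess")
    manifest$outputs <- c(manifest$outputs, "dataset", "provenance.json")

    if (!is.null(config$analysis)) {
      res <- stage_analysis(ds, config$analysis, config$seed, out,
                            config$style %||% list(), logfile)
      manifest$completed <- c(manifest$completed, "analysis")
      manifest$outputs <- c(manifest$outputs, res)
    }

    if (!anyNA(ds$mat) && nrow(ds$mat) >= 3 && ncol(ds$mat) >= 2) {
      pc <- pca_analysis(ds, n_components = 2L)
      write_result_tsv(tidy.lfq_pca(pc), file.path(out, "pca_scores.tsv"))
      render_svg(pc, file.path(out, "pca.svg"), config$style %||% list())
      manifest$completed <- c(manifest$completed, "pca")
      manifest$outputs <- c(manifest$outputs, "pca_scores.tsv", "pca.svg")
    }
    finish()
    log_msg("INFO", paste0("done: ", out), logfile)
    invisible(manifest$outputs)
  }, error = function(e) {
    manifest$failed <<- conditionMessage(e)
    finish()
    log_msg("ERROR", conditionMessage(e), logfile)
    stop(e)
  })
}

apply_config_step <- function(ds, st, seed) {
  switch(st$step,
    remove_contaminants = remove_contaminants(ds),
    zero_to_missing = zero_to_missing(ds),
    filter_completeness = filter_completeness(ds,
                                              st$min_fraction %||% 0.5),
    log2_transform = log2_transform(ds),
    normalize = normalize_intensities(ds, st$method %||% "median_center"),
    impute = impute_intensities(ds, st$method %||% "knn", seed = seed,
                                k = st$k %||% 3L,
                                n_estimators = st$n_estimators %||% 100L,
                                max_iter = st$max_iter %||% 10L))
}

#' Pipeline stages
#'
#' Each stage runs one piece of the pipeline and can resume from a directory
#' written by [save_dataset()], so analyses can be chained from the command
#' line; chaining the stages is equivalent to one [run_pipeline()] call.
#'
#' @param input Protein table path.
#' @param dialect Dialect name or `"auto"`.
#' @param metadata Metadata path (CSV/TSV by extension) or data frame.
#' @param sample_column Metadata column with sample ids.
#' @param intensity_preference Optional intensity-family override.
#' @param contaminants Optional path to a file of extra contaminant
#'   accessions (one per line).
#' @return `stage_import()` returns an [lfq_dataset].
#' @export
stage_import <- function(input, dialect = "auto", metadata,
                         sample_column = "sample",
                         intensity_preference = NULL, contaminants = NULL) {
  dia <- if (identical(dialect, "auto")) {
    detect_dialect(readLines(input, n = 5L, warn = FALSE))
  } else {
    engine_dialect(dialect)
  }
  tab <- load_table(input, dia,
                    intensity_preference = unlist(intensity_preference))
  extra <- NULL
  if (!is.null(contaminants)) {
    if (!file.exists(contaminants)) {
      abort(paste0("contaminant list not found: ", contaminants))
    }
    extra <- trimws(readLines(contaminants, warn = FALSE))
    extra <- extra[nzchar(extra)]
  }
  tab <- flag_contaminants(tab, extra)
  md <- if (is.character(metadata)) read_metadata(metadata) else metadata
  create_dataset(tab, md, sample_column)
}

#' Read a sample-metadata table (CSV or TSV by extension)
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata not found: ", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' @rdname stage_import
#' @param dataset_dir Directory written by [save_dataset()].
#' @param steps List of preprocessing step entries (as in the config).
#' @param out_dir Output directory.
#' @param seed Seed for stochastic steps.
#' @return `stage_preprocess()` returns the output directory, invisibly.
#' @export
stage_preprocess <- function(dataset_dir, steps, out_dir, seed = 0L) {
  ds <- stage_load(dataset_dir)
  for (st in steps) ds <- apply_config_step(ds, st, seed)
  save_dataset(ds, out_dir)
  invisible(out_dir)
}

stage_load <- function(dataset_dir) {
  if (!file.exists(file.path(dataset_dir, "matrix.tsv"))) {
    abort(paste0("expected a serialized dataset at ", dataset_dir,
                 " (missing matrix.tsv); run the import stage first"))
  }
  load_dataset(dataset_dir)
}

#' @rdname stage_import
#' @param analysis Analysis spec: list with `test`, `group_column`,
#'   `group1`/`group2` (two-group tests), `covariates` (ancova), `min_obs`,
#'   `fc_cutoff`, `alpha`, `use_adjusted`, `n_perm`/`delta`/`s0` (sam).
#' @param style SVG style list.
#' @param logfile Optional log file.
#' @return `stage_analysis()` returns the vector of files written (relative
#'   to `out_dir`).
#' @export
stage_analysis <- function(dataset_dir, analysis, seed = 0L, out_dir,
                           style = list(), logfile = NULL) {
  ds <- if (inherits(dataset_dir, "lfq_dataset")) dataset_dir else
    stage_load(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- analysis
  written <- character()
  if (an$test %in% c("ttest", "welch_ttest")) {
    de <- de_ttest(ds, an$group_column, an$group1, an$group2,
                   equal_var = identical(an$test, "ttest"),
                   min_obs = an$min_obs %||% 2L)
  } else if (an$test == "anova") {
    de <- de_anova(ds, an$group_column, min_obs = an$min_obs %||% 2L)
  } else if (an$test == "ancova") {
    de <- de_ancova(ds, an$group_column, unlist(an$covariates),
                    min_obs = an$min_obs %||% 2L)
  } else if (an$test == "sam") {
    fit <- sam(ds, an$group_column, an$group1, an$group2,
               n_perm = an$n_perm %||% 1000L, delta = an$delta,
               s0_mode = an$s0_mode %||% "auto", s0_value = an$s0,
               seed = seed)
    write_result_tsv(tidy.sam_result(fit),
                     file.path(out_dir, "sam_results.tsv"))
    write_result_tsv(sam_delta_table(fit),
                     file.path(out_dir, "sam_delta_table.tsv"))
    return(c("sam_results.tsv", "sam_delta_table.tsv"))
  }
  write_result_tsv(tidy.de_result(de), file.path(out_dir, "de_results.tsv"))
  written <- "de_results.tsv"
  if (an$test %in% c("ttest", "welch_ttest")) {
    vd <- volcano_data(de, fc_cutoff = an$fc_cutoff %||% 1,
                       alpha = an$alpha %||% 0.05,
                       use_adjusted = isTRUE(an$use_adjusted))
    write_result_tsv(as_tibble(vd), file.path(out_dir, "volcano_data.tsv"))
    render_svg(vd, file.path(out_dir, "volcano.svg"), style)
    written <- c(written, "volcano_data.tsv", "volcano.svg")
  }
  written
}

#' @rdname stage_import
#' @param design_path YAML spike-in design (see [write_spikein_design()]).
#' @param ... Forwarded to [compare_pipelines()].
#' @return `stage_benchmark()` returns the benchmark tibble, invisibly,
#'   after writing `benchmark.tsv`.
#' @export
stage_benchmark <- function(design_path, out_dir, ...) {
  design <- read_spikein_design(design_path)
  res <- compare_pipelines(design, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_result_tsv(res, file.path(out_dir, "benchmark.tsv"))
  invisible(res)
}
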