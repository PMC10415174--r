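#' Search-engine dialect registry
#'
#' Each supported quantification software writes protein tables with its own
#' column conventions. A dialect bundles everything the loader needs: the
#' protein-group identifier column, the rule that extracts sample names from
#' intensity column headers, the table orientation (wide or long), and the
#' contaminant-flagging rules (marker columns and accession prefixes).
#'
#' @param name One of `"maxquant"`, `"diann"`, `"fragpipe"`, `"spectronaut"`,
#'   `"alphapept"`, `"mztab"`, `"generic"`.
#' @return An object of class `engine_dialect`: a list with fields `name`,
#'   `id_column` (character vector, first match wins), `orientation`,
#'   `intensity_prefixes` / `intensity_suffixes` (column families in
#'   preference order), `marker_columns` (columns where a `"+"` flags a
#'   contaminant), `contaminant_prefixes`, `sep` (field separator), and for
#'   long dialects the key columns.
#' @examples
#' engine_dialect("maxquant")$id_column
#' @export
engine_dialect <- function(name) {
  name <- match.arg(name, dialect_names())
  d <- switch(name,
    maxquant = list(
      id_column = c("Majority protein IDs", "Protein IDs"),
      orientation = "wide",
      intensity_prefixes = c("LFQ intensity ", "Intensity "),
      intensity_suffixes = character(),
      marker_columns = c("Potential contaminant", "Contaminant",
                         "Reverse", "Only identified by site"),
      contaminant_prefixes = c("CON__", "REV__"),
      sep = "\t"
    ),
    diann = list(
      id_column = "Protein.Group",
      orientation = "wide",
      # every column after the fixed annotation block is a run; sample name
      # is the basename of the run path without extension
      annotation_block = c("Protein.Group", "Protein.Ids", "Protein.Names",
                           "Genes", "First.Protein.Description"),
      intensity_prefixes = character(),
      intensity_suffixes = character(),
      marker_columns = character(),
      contaminant_prefixes = c("CON__", "REV__"),
      sep = "\t"
    ),
    fragpipe = list(
      id_column = "Protein",
      orientation = "wide",
      intensity_prefixes = character(),
      intensity_suffixes = c(" MaxLFQ Intensity", " Intensity"),
      marker_columns = character(),
      contaminant_prefixes = c("CON__", "contam_", "REV__"),
      sep = "\t"
    ),
    spectronaut = list(
      id_column = "PG.ProteinGroups",
      orientation = "long",
      long_sample_column = "R.FileName",
      long_value_column = "PG.Quantity",
      intensity_prefixes = character(),
      intensity_suffixes = character(),
      marker_columns = character(),
      contaminant_prefixes = c("CON__", "REV__"),
      sep = "\t"
    ),
    alphapept = list(
      id_column = "protein_group",
      orientation = "wide",
      intensity_prefixes = character(),
      intensity_suffixes = character(),
      marker_columns = character(),
      contaminant_prefixes = c("CON__", "REV__"),
      sep = ","
    ),
    mztab = list(
      id_column = "accession",
      orientation = "wide",
      intensity_prefixes = character(),
      intensity_suffixes = character(),
      marker_columns = character(),
      contaminant_prefixes = c("CON__", "REV__"),
      sep = "\t"
    ),
    generic = list(
      id_column = NA_character_, # first column of the file
      orientation = "wide",
      intensity_prefixes = character(),
      intensity_suffixes = character(),
      marker_columns = character(),
      contaminant_prefixes = c("CON__", "REV__"),
      sep = NA_character_ # sniffed from the header line
    )
  )
  d$name <- name
  structure(d, class = "engine_dialect")
}

dialect_names <- function() {
  c("maxquant", "diann", "fragpipe", "spectronaut", "alphapept",
    "mztab", "generic")
}

#' @export
print.engine_dialect <- function(x, ...) {
  cat("<engine_dialect> ", x$name, " (", x$orientation, ")\n", sep = "")
  invisible(x)
}

split_header <- function(line, sep) strsplit(line, sep, fixed = TRUE)[[1]]

sniff_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Detect the search-engine dialect of a protein table
#'
#' Inspects header lines (the first line, plus optionally a few body lines)
#' and returns the dialect whose signature columns match. Exactly one dialect
#' must match; an mzTab file is recognised by its `MTD`/`PRH`/`PRT` section
#' codes. When no engine signature is found but the header has one leading
#' identifier column followed by columns whose body cells are numeric, the
#' `generic` dialect is returned.
#'
#' @param header_lines Character vector: the first line(s) of the file.
#' @return An [engine_dialect()].
#' @examples
#' detect_dialect("Majority protein IDs\tLFQ intensity A\tLFQ intensity B")
#' detect_dialect(c("id,v1,v2", "P1,3.5,4.0"))
#' @export
detect_dialect <- function(header_lines) {
  header_lines <- header_lines[nzchar(trimws(header_lines))]
  if (length(header_lines) == 0) {
    stop("detect_dialect() needs at least one nonempty line", call. = FALSE)
  }
  first <- header_lines[[1]]
  prefixes3 <- substr(header_lines, 1, 3)

  candidates <- character()
  if (any(prefixes3 %in% c("MTD", "PRH", "PRT"))) {
    candidates <- c(candidates, "mztab")
  }
  fields_tab <- split_header(first, "\t")
  fields_csv <- split_header(first, ",")
  has <- function(col) col %in% fields_tab || col %in% fields_csv
  if (has("Majority protein IDs") ||
      (has("Protein IDs") && any(startsWith(fields_tab, "LFQ intensity ")))) {
    candidates <- c(candidates, "maxquant")
  }
  if (has("Protein.Group")) candidates <- c(candidates, "diann")
  if (has("Protein") && any(endsWith(fields_tab, " Intensity"))) {
    candidates <- c(candidates, "fragpipe")
  }
  if (has("PG.ProteinGroups")) candidates <- c(candidates, "spectronaut")
  if (has("protein_group")) candidates <- c(candidates, "alphapept")

  if (length(candidates) > 1) {
    stop("ambiguous format: header matches dialects ",
         paste(candidates, collapse = ", "), call. = FALSE)
  }
  if (length(candidates) == 1) return(engine_dialect(candidates))

  # generic fallback: one id-like leading column, >= 1 numeric column
  sep <- sniff_sep(first)
  fields <- split_header(first, sep)
  if (length(fields) >= 2) {
    body <- header_lines[-1]
    body_numeric <- TRUE
    if (length(body) > 0) {
      cells <- split_header(body[[1]], sep)[-1]
      vals <- suppressWarnings(as.numeric(cells))
      body_numeric <- length(vals) > 0 && !all(is.na(vals))
    }
    if (body_numeric) return(engine_dialect("generic"))
  }
  stop("unrecognized format: header matches no known dialect and is not a ",
       "generic id + numeric-columns table", call. = FALSE)
}
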