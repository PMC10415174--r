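#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd na.omit setNames quantile
#' @importFrom utils head combn
NULL

#' Raw protein table
#'
#' Canonical parsed form of a search-engine protein output: one row per
#' protein group, one intensity column per sample, annotations carried along
#' and a per-protein contaminant flag.
#'
#' @param protein_ids Character vector of unique protein-group identifiers.
#' @param intensities Numeric matrix, proteins x samples; `NA` = missing,
#'   present values must be non-negative.
#' @param sample_names Character vector of unique sample labels.
#' @param annotations Tibble with a `protein_id` column plus any annotation
#'   columns (gene names, marker columns, ...).
#' @param contaminant Logical vector per protein.
#' @param source_dialect Name of the originating [engine_dialect()].
#' @return An object of class `raw_protein_table`.
#' @export
raw_protein_table <- function(protein_ids, intensities, sample_names,
                              annotations = NULL, contaminant = NULL,
                              source_dialect = "generic") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- list(protein_ids, sample_names)
  if (is.null(annotations)) annotations <- tibble(protein_id = protein_ids)
  if (is.null(contaminant)) contaminant <- rep(FALSE, length(protein_ids))
  x <- structure(
    list(protein_ids = protein_ids, intensities = intensities,
         sample_names = sample_names, annotations = annotations,
         contaminant = contaminant, source_dialect = source_dialect),
    class = "raw_protein_table")
  validate_raw_protein_table(x)
}

#' Validate a raw protein table against its invariants
#'
#' Checks identifier uniqueness, matrix shape and non-negativity of observed
#' intensities; errors on the first violation.
#'
#' @param x A [raw_protein_table()].
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_raw_protein_table <- function(x) {
  stopifnot(inherits(x, "raw_protein_table"))
  if (anyDuplicated(x$protein_ids)) {
    abort(paste0("duplicate protein ids: ",
                 paste(unique(x$protein_ids[duplicated(x$protein_ids)]),
                       collapse = ", ")))
  }
  if (anyDuplicated(x$sample_names)) {
    abort(paste0("duplicate sample names: ",
                 paste(unique(x$sample_names[duplicated(x$sample_names)]),
                       collapse = ", ")))
  }
  if (!identical(dim(x$intensities),
                 c(length(x$protein_ids), length(x$sample_names)))) {
    abort("intensity matrix shape does not match protein/sample counts")
  }
  if (any(x$intensities < 0, na.rm = TRUE)) {
    abort("negative intensities are not valid")
  }
  if (length(x$contaminant) != length(x$protein_ids)) {
    abort("contaminant flag length does not match protein count")
  }
  invisible(x)
}

#' @export
print.raw_protein_table <- function(x, ...) {
  cat("<raw_protein_table> ", length(x$protein_ids), " protein groups x ",
      length(x$sample_names), " samples [", x$source_dialect, "]\n", sep = "")
  cat("  contaminant-flagged: ", sum(x$contaminant), "\n", sep = "")
  invisible(x)
}

#' @rdname raw_protein_table
#' @param x A `raw_protein_table`.
#' @param ... Unused.
#' @method tidy raw_protein_table
#' @export
tidy.raw_protein_table <- function(x, ...) {
  as_tibble(x$intensities, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample",
                        values_to = "intensity")
}

read_delim_chr <- function(path, sep) {
  readr::read_delim(path, delim = sep, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE,
                    show_col_types = FALSE, name_repair = "minimal")
}

# strict numeric conversion of intensity cells; blanks and NA tokens -> NA,
# anything else non-numeric is a parse error naming the cell
parse_intensity <- function(cells, column, ids) {
  cells <- trimws(cells)
  missing_tokens <- c("", "NA", "NaN", "nan", "null", "Filtered", "#N/A")
  out <- rep(NA_real_, length(cells))
  todo <- !(cells %in% missing_tokens)
  vals <- suppressWarnings(as.numeric(cells[todo]))
  bad <- which(is.na(vals))
  if (length(bad) > 0) {
    i <- which(todo)[bad[1]]
    abort(sprintf("non-numeric intensity '%s' at row %d (%s), column '%s'",
                  cells[i], i, ids[i], column))
  }
  out[todo] <- vals
  out
}

pick_intensity_columns <- function(cols, dialect, intensity_preference) {
  if (dialect$name == "maxquant" ||
      length(dialect$intensity_prefixes) > 0) {
    prefs <- intensity_preference %||% dialect$intensity_prefixes
    for (pref in prefs) {
      hit <- cols[startsWith(cols, pref)]
      if (length(hit) > 0) {
        return(list(columns = hit,
                    samples = substring(hit, nchar(pref) + 1)))
      }
    }
    abort(paste0("no intensity columns found for families: ",
                 paste(prefs, collapse = ", ")))
  }
  if (length(dialect$intensity_suffixes) > 0) {
    prefs <- intensity_preference %||% dialect$intensity_suffixes
    taken <- character()
    for (pref in prefs) {
      hit <- setdiff(cols[endsWith(cols, pref)], taken)
      # " Intensity" also matches " MaxLFQ Intensity" columns; a column
      # belongs to the most specific family only
      longer <- prefs[nchar(prefs) > nchar(pref) & endsWith(prefs, pref)]
      for (lg in longer) hit <- hit[!endsWith(hit, lg)]
      if (length(hit) > 0) {
        return(list(columns = hit,
                    samples = substr(hit, 1, nchar(hit) - nchar(pref))))
      }
      taken <- c(taken, hit)
    }
    abort(paste0("no intensity columns found for families: ",
                 paste(prefs, collapse = ", ")))
  }
  abort("dialect has no intensity column family")
}

#' Load a protein quantification table
#'
#' Parses a search-engine output file into a [raw_protein_table()]. For wide
#' dialects one intensity column family is selected (by `intensity_preference`
#' or the dialect default, e.g. LFQ over raw intensity for MaxQuant) and
#' sample names are stripped of the family prefix/suffix. The long Spectronaut
#' report is pivoted to wide, leaving missing cells where a (protein, sample)
#' pair was not observed. Contaminant flags are initialised to `FALSE`; apply
#' [flag_contaminants()] afterwards.
#'
#' @param path Path to the file.
#' @param dialect An [engine_dialect()], its name, or `NULL` to auto-detect.
#' @param intensity_preference Optional ordered character vector of intensity
#'   column families overriding the dialect default.
#' @return A [raw_protein_table()].
#' @export
load_table <- function(path, dialect = NULL, intensity_preference = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(dialect)) {
    dialect <- detect_dialect(readLines(path, n = 5L, warn = FALSE))
  }
  if (is.character(dialect)) dialect <- engine_dialect(dialect)
  if (dialect$name == "mztab") return(load_mztab(path))

  sep <- dialect$sep
  if (is.na(sep)) sep <- sniff_sep(readLines(path, n = 1L, warn = FALSE))
  df <- read_delim_chr(path, sep)
  cols <- names(df)

  if (dialect$name == "spectronaut") {
    return(pivot_long_report(df, dialect))
  }

  id_col <- if (all(is.na(dialect$id_column))) cols[[1]] else
    intersect(dialect$id_column, cols)[1]
  if (is.na(id_col) || !id_col %in% cols) {
    abort(paste0("format error: missing id column ",
                 paste(dialect$id_column, collapse = " / ")))
  }
  protein_ids <- trimws(df[[id_col]])
  if (anyDuplicated(protein_ids)) {
    abort(paste0("duplicate protein-group rows: ",
                 paste(unique(protein_ids[duplicated(protein_ids)]),
                       collapse = ", ")))
  }

  if (dialect$name == "diann") {
    run_cols <- setdiff(cols, dialect$annotation_block)
    samples <- tools::file_path_sans_ext(basename(run_cols))
    sel <- list(columns = run_cols, samples = samples)
  } else if (dialect$name %in% c("alphapept", "generic")) {
    other <- setdiff(cols, id_col)
    numericish <- vapply(other, function(cn) {
      v <- trimws(df[[cn]])
      v <- v[!(v %in% c("", "NA", "NaN", "null"))]
      length(v) == 0 || !anyNA(suppressWarnings(as.numeric(v)))
    }, logical(1))
    sel <- list(columns = other[numericish], samples = other[numericish])
    if (length(sel$columns) == 0) abort("no numeric intensity columns found")
  } else {
    sel <- pick_intensity_columns(cols, dialect, intensity_preference)
  }
  if (anyDuplicated(sel$samples)) {
    abort(paste0("sample name collision after stripping: ",
                 paste(unique(sel$samples[duplicated(sel$samples)]),
                       collapse = ", ")))
  }

  mat <- vapply(seq_along(sel$columns), function(j) {
    parse_intensity(df[[sel$columns[j]]], sel$columns[j], protein_ids)
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)

  ann_cols <- setdiff(cols, c(sel$columns, id_col))
  # drop unselected intensity families from annotations
  for (pref in c(dialect$intensity_prefixes)) {
    ann_cols <- ann_cols[!startsWith(ann_cols, pref)]
  }
  for (suf in c(dialect$intensity_suffixes)) {
    ann_cols <- ann_cols[!endsWith(ann_cols, suf)]
  }
  ann <- dplyr::bind_cols(tibble(protein_id = protein_ids),
                          df[, ann_cols, drop = FALSE])

  raw_protein_table(protein_ids, mat, sel$samples, annotations = ann,
                    source_dialect = dialect$name)
}

pivot_long_report <- function(df, dialect) {
  need <- c(dialect$id_column, dialect$long_sample_column,
            dialect$long_value_column)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("format error: missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  pid <- trimws(df[[dialect$id_column]])
  smp <- trimws(df[[dialect$long_sample_column]])
  key <- paste(pid, smp, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    abort(paste0("duplicate (protein, sample) pair in long report: ",
                 gsub("\r", " / ", d, fixed = TRUE)))
  }
  vals <- parse_intensity(df[[dialect$long_value_column]],
                          dialect$long_value_column, pid)
  protein_ids <- unique(pid)
  sample_names <- unique(smp)
  mat <- matrix(NA_real_, length(protein_ids), length(sample_names),
                dimnames = list(protein_ids, sample_names))
  mat[cbind(match(pid, protein_ids), match(smp, sample_names))] <- vals

  ann_cols <- setdiff(names(df), need)
  ann <- tibble(protein_id = protein_ids)
  if (length(ann_cols) > 0) {
    first <- df[match(protein_ids, pid), ann_cols, drop = FALSE]
    ann <- dplyr::bind_cols(ann, first)
  }
  raw_protein_table(protein_ids, mat, sample_names, annotations = ann,
                    source_dialect = dialect$name)
}

#' Load an mzTab file
#'
#' Reads the metadata (`MTD`) and protein (`PRH`/`PRT`) sections of an mzTab
#' document. Protein rows become proteins; columns named
#' `protein_abundance_assay[n]` become samples. Sample names are resolved
#' through `assay[n]-sample_ref` to the referenced `sample[k]-description`
#' when the metadata provides one, otherwise `assay[n]` is used. `null` cells
#' become missing values. Peptide and PSM sections are ignored.
#'
#' @param path Path to the mzTab file.
#' @return A [raw_protein_table()].
#' @export
load_mztab <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tag <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)

  prt <- lines[tag == "PRT"]
  prh <- lines[tag == "PRH"]
  if (length(prt) == 0) abort("mzTab file contains no PRT protein rows")
  if (length(prh) != 1) abort("mzTab file must contain exactly one PRH line")

  header <- strsplit(prh, "\t", fixed = TRUE)[[1]][-1]
  rows <- lapply(strsplit(prt, "\t", fixed = TRUE), function(x) x[-1])
  nbad <- which(lengths(rows) != length(header))
  if (length(nbad) > 0) {
    abort(sprintf("PRH/PRT column-count mismatch at PRT row %d (%d vs %d)",
                  nbad[1], lengths(rows)[nbad[1]], length(header)))
  }
  tab <- as_tibble(setNames(as.data.frame(do.call(rbind, rows),
                                          stringsAsFactors = FALSE), header))

  ab_cols <- grep("^protein_abundance_assay\\[\\d+\\]$", header, value = TRUE)
  if (length(ab_cols) == 0) {
    abort(paste0("no protein_abundance_assay[n] columns found; ",
                 "use the generic loader for plain tables"))
  }
  assay_n <- sub("^protein_abundance_assay\\[(\\d+)\\]$", "\\1", ab_cols)

  # MTD lookups: assay[n]-sample_ref -> sample[k]; sample[k]-description
  mtd <- strsplit(lines[tag == "MTD"], "\t", fixed = TRUE)
  mtd <- mtd[lengths(mtd) >= 3]
  keys <- vapply(mtd, `[[`, character(1), 2)
  vals <- vapply(mtd, `[[`, character(1), 3)
  sample_names <- vapply(assay_n, function(n) {
    ref <- vals[keys == sprintf("assay[%s]-sample_ref", n)]
    if (length(ref) == 1) {
      desc <- vals[keys == paste0(ref, "-description")]
      if (length(desc) == 1 && nzchar(desc)) return(desc)
    }
    sprintf("assay[%s]", n)
  }, character(1))

  id_col <- if ("accession" %in% header) "accession" else header[[1]]
  protein_ids <- trimws(tab[[id_col]])
  if (anyDuplicated(protein_ids)) {
    abort("duplicate protein accession rows in PRT section")
  }
  mat <- vapply(ab_cols, function(cn) {
    parse_intensity(tab[[cn]], cn, protein_ids)
  }, numeric(nrow(tab)))
  if (nrow(tab) == 1L) mat <- matrix(mat, nrow = 1L)

  ann <- dplyr::bind_cols(tibble(protein_id = protein_ids),
                          tab[, setdiff(header, c(ab_cols, id_col)),
                              drop = FALSE])
  raw_protein_table(protein_ids, mat, unname(sample_names), annotations = ann,
                    source_dialect = "mztab")
}

#' Flag contaminant protein groups
#'
#' Sets the contaminant flag wherever the source dialect's rules fire —
#' marker columns carrying a `"+"` (e.g. MaxQuant's "Potential contaminant"
#' and "Reverse") or identifier prefixes such as `CON__`/`REV__` on any
#' accession inside the protein group — or where the identifier intersects
#' `extra_accessions`. Existing flags are never cleared, so the operation is
#' idempotent. The input table is not modified.
#'
#' @param table A [raw_protein_table()].
#' @param extra_accessions Optional character vector of additional
#'   contaminant accessions.
#' @return A new `raw_protein_table` with updated flags.
#' @export
flag_contaminants <- function(table, extra_accessions = NULL) {
  stopifnot(inherits(table, "raw_protein_table"))
  dialect <- engine_dialect(table$source_dialect)
  flags <- table$contaminant

  for (mc in intersect(dialect$marker_columns, names(table$annotations))) {
    flags <- flags | (trimws(table$annotations[[mc]]) == "+")
  }
  accs <- strsplit(table$protein_ids, ";", fixed = TRUE)
  for (pref in dialect$contaminant_prefixes) {
    flags <- flags | vapply(accs, function(a) any(startsWith(a, pref)),
                            logical(1))
  }
  if (!is.null(extra_accessions) && length(extra_accessions) > 0) {
    flags <- flags | table$protein_ids %in% extra_accessions |
      vapply(accs, function(a) any(a %in% extra_accessions), logical(1))
  }
  out <- table
  out$contaminant <- unname(flags)
  out
}
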