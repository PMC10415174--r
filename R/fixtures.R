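# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         format(x, scientific = FALSE, trim = TRUE, digits = 15))
}

#' Write a synthetic search-engine fixture file
#'
#' Emits a small, syntactically valid protein table in any supported dialect,
#' filled with seeded pseudo-random integer intensities, and returns the exact
#' values written so a loader can be verified cell by cell. When
#' `n_proteins >= 2` the second protein is written as a contaminant (a
#' `CON__` accession, plus the dialect's marker column where one exists). A
#' JSON manifest of the written values is placed next to the file.
#'
#' @param dialect Dialect name or [engine_dialect()].
#' @param n_proteins,n_samples Positive counts.
#' @param seed Integer seed; equal seeds give byte-identical files.
#' @param path Output file path.
#' @return Invisibly, the manifest: a list with `dialect`, `protein_ids`,
#'   `sample_names`, `values` (proteins x samples matrix), `contaminant_ids`
#'   and `path`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' man <- make_fixture_file("maxquant", 3, 2, seed = 1, path = f)
#' tab <- load_table(f, "maxquant")
#' all.equal(unname(tab$intensities), unname(man$values))
#' @export
make_fixture_file <- function(dialect, n_proteins, n_samples, seed, path) {
  if (is.character(dialect)) dialect <- engine_dialect(dialect)
  if (!inherits(dialect, "engine_dialect")) abort("unsupported dialect")
  stopifnot(n_proteins >= 1, n_samples >= 1)

  protein_ids <- sprintf("P%05d", seq_len(n_proteins))
  contaminant_ids <- character()
  if (n_proteins >= 2) {
    protein_ids[2] <- paste0("CON__", protein_ids[2])
    contaminant_ids <- protein_ids[2]
  }
  sample_names <- sprintf("S%02d", seq_len(n_samples))
  genes <- sprintf("GENE%d", seq_len(n_proteins))

  values <- with_seed(seed, matrix(
    as.numeric(sample.int(9e6L, n_proteins * n_samples, replace = TRUE)) + 1e5,
    n_proteins, n_samples, dimnames = list(protein_ids, sample_names)))
  # a second, deliberately different column family for multi-family dialects
  alt_values <- values * 2

  lines <- switch(dialect$name,
    maxquant = {
      header <- c("Protein IDs", "Majority protein IDs", "Gene names",
                  paste0("LFQ intensity ", sample_names),
                  paste0("Intensity ", sample_names),
                  "Potential contaminant", "Reverse")
      body <- vapply(seq_len(n_proteins), function(i) {
        paste(c(protein_ids[i], protein_ids[i], genes[i],
                fmt_num(values[i, ]), fmt_num(alt_values[i, ]),
                if (protein_ids[i] %in% contaminant_ids) "+" else "", ""),
              collapse = "\t")
      }, character(1))
      c(paste(header, collapse = "\t"), body)
    },
    diann = {
      header <- c("Protein.Group", "Protein.Ids", "Protein.Names", "Genes",
                  "First.Protein.Description",
                  paste0("/raw/", sample_names, ".d"))
      body <- vapply(seq_len(n_proteins), function(i) {
        paste(c(protein_ids[i], protein_ids[i], paste0(genes[i], "_HUMAN"),
                genes[i], paste0("Protein ", i), fmt_num(values[i, ])),
              collapse = "\t")
      }, character(1))
      c(paste(header, collapse = "\t"), body)
    },
    fragpipe = {
      header <- c("Protein", "Protein ID", "Gene",
                  paste0(sample_names, " Intensity"),
                  paste0(sample_names, " MaxLFQ Intensity"))
      body <- vapply(seq_len(n_proteins), function(i) {
        paste(c(protein_ids[i], sub("^CON__", "", protein_ids[i]), genes[i],
                fmt_num(alt_values[i, ]), fmt_num(values[i, ])),
              collapse = "\t")
      }, character(1))
      c(paste(header, collapse = "\t"), body)
    },
    spectronaut = {
      header <- c("PG.ProteinGroups", "PG.Genes", "R.FileName", "PG.Quantity")
      grid <- expand.grid(i = seq_len(n_proteins), j = seq_len(n_samples))
      body <- vapply(seq_len(nrow(grid)), function(r) {
        i <- grid$i[r]; j <- grid$j[r]
        paste(c(protein_ids[i], genes[i], sample_names[j],
                fmt_num(values[i, j])), collapse = "\t")
      }, character(1))
      c(paste(header, collapse = "\t"), body)
    },
    alphapept = {
      header <- c("protein_group", "gene_names", sample_names)
      body <- vapply(seq_len(n_proteins), function(i) {
        paste(c(protein_ids[i], genes[i], fmt_num(values[i, ])),
              collapse = ",")
      }, character(1))
      c(paste(header, collapse = ","), body)
    },
    mztab = {
      mtd <- c("MTD\tmzTab-version\t1.0.0",
               "MTD\tmzTab-mode\tSummary",
               "MTD\tmzTab-type\tQuantification",
               "MTD\tdescription\tsynthetic fixture",
               vapply(seq_len(n_samples), function(j) {
                 sprintf("MTD\tsample[%d]-description\t%s", j,
                         sample_names[j])
               }, character(1)),
               vapply(seq_len(n_samples), function(j) {
                 sprintf("MTD\tassay[%d]-sample_ref\tsample[%d]", j, j)
               }, character(1)))
      prh <- paste(c("PRH", "accession", "description",
                     sprintf("protein_abundance_assay[%d]",
                             seq_len(n_samples))), collapse = "\t")
      prt <- vapply(seq_len(n_proteins), function(i) {
        paste(c("PRT", protein_ids[i], paste0("Protein ", i),
                fmt_num(values[i, ])), collapse = "\t")
      }, character(1))
      c(mtd, prh, prt)
    },
    generic = {
      header <- c("id", sample_names)
      body <- vapply(seq_len(n_proteins), function(i) {
        paste(c(protein_ids[i], fmt_num(values[i, ])), collapse = ",")
      }, character(1))
      c(paste(header, collapse = ","), body)
    },
    abort(paste0("unsupported dialect: ", dialect$name))
  )

  writeLines(lines, path, useBytes = TRUE)
  manifest <- list(dialect = dialect$name, protein_ids = protein_ids,
                   sample_names = sample_names, values = values,
                   contaminant_ids = contaminant_ids, path = path)
  jsonlite::write_json(
    list(dialect = dialect$name, protein_ids = protein_ids,
         sample_names = sample_names,
         values = as.data.frame(values),
         contaminant_ids = contaminant_ids),
    paste0(path, ".manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
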