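test_that("dialect detection recognises engine signatures and falls back to generic", {
  expect_equal(
    detect_dialect("Majority protein IDs\tLFQ intensity A\tLFQ intensity B")$name,
    "maxquant")
  expect_equal(detect_dialect(c("MTD\tmzTab-version\t1.0.0",
                                "PRH\taccession"))$name, "mztab")
  expect_equal(detect_dialect("Protein.Group\tGenes\t/raw/a.d")$name, "diann")
  expect_equal(
    detect_dialect("Protein\tGene\tS1 Intensity\tS1 MaxLFQ Intensity")$name,
    "fragpipe")
  expect_equal(
    detect_dialect("PG.ProteinGroups\tR.FileName\tPG.Quantity")$name,
    "spectronaut")
  expect_equal(detect_dialect("protein_group,gene_names,S1,S2")$name,
               "alphapept")
  expect_equal(detect_dialect(c("id,v1,v2", "P1,3.5,4.0"))$name, "generic")
  # two engine signatures in one header is an ambiguity, not a guess
  expect_error(
    detect_dialect("Majority protein IDs\tProtein.Group\tLFQ intensity A"),
    "ambiguous")
  expect_error(detect_dialect("   "), "nonempty")
  expect_error(detect_dialect("justoneword"), "unrecognized")
})

test_that("every dialect round-trips its fixture cell-for-cell in order", {
  for (d in c("maxquant", "diann", "fragpipe", "spectronaut", "alphapept",
              "mztab", "generic")) {
    f <- withr::local_tempfile(fileext = ".txt")
    man <- make_fixture_file(d, 5, 3, seed = 11, path = f)
    tab <- if (d == "mztab") load_mztab(f) else load_table(f, d)
    expect_s3_class(validate_raw_protein_table(tab), "raw_protein_table")
    expect_identical(tab$protein_ids, man$protein_ids)
    expect_identical(tab$sample_names, man$sample_names)
    expect_identical(unname(tab$intensities), unname(man$values))
    # auto-detection resolves the written file to the same dialect
    expect_equal(detect_dialect(readLines(f, n = 3))$name, d)
  }
})

test_that("fixture files are byte-identical under the same seed", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  make_fixture_file("diann", 4, 3, seed = 9, path = f1)
  make_fixture_file("diann", 4, 3, seed = 9, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(make_fixture_file("unknown_engine", 2, 2, 1, tempfile()))
})

test_that("maxquant loader honours the intensity family preference", {
  f <- withr::local_tempfile()
  man <- make_fixture_file("maxquant", 3, 2, seed = 4, path = f)
  lfq <- load_table(f, "maxquant")
  raw <- load_table(f, "maxquant", intensity_preference = "Intensity ")
  expect_identical(unname(lfq$intensities), unname(man$values))
  # fixture writes the raw Intensity family as exactly twice the LFQ values
  expect_identical(unname(raw$intensities), unname(man$values * 2))
})

test_that("long-format pivot conserves data and rejects duplicates", {
  f <- withr::local_tempfile()
  writeLines(c("PG.ProteinGroups\tPG.Genes\tR.FileName\tPG.Quantity",
               "P1\tG1\trunA\t100.5",
               "P1\tG1\trunB\t200",
               "P2\tG2\trunA\t50",
               "P2\tG2\trunC\t75"), f)
  tab <- load_table(f, "spectronaut")
  expect_equal(dim(tab$intensities), c(2, 3))
  # conservation: non-missing cells == numeric long rows
  expect_equal(sum(!is.na(tab$intensities)), 4)
  expect_equal(tab$intensities["P1", "runA"], 100.5)
  expect_true(is.na(tab$intensities["P2", "runB"]))

  writeLines(c("PG.ProteinGroups\tR.FileName\tPG.Quantity",
               "P1\trunA\t1", "P1\trunA\t2"), f)
  expect_error(load_table(f, "spectronaut"), "duplicate")
})

test_that("loader errors name the offending column or cell", {
  f <- withr::local_tempfile()
  writeLines(c("WrongId\tLFQ intensity A", "P1\t5"), f)
  expect_error(load_table(f, "maxquant"), "Majority protein IDs")

  writeLines(c("Majority protein IDs\tLFQ intensity A\tLFQ intensity B",
               "P1\t5\toops"), f)
  expect_error(load_table(f, "maxquant"), "oops")

  writeLines(c("Majority protein IDs\tLFQ intensity A", "P1\t5", "P1\t6"), f)
  expect_error(load_table(f, "maxquant"), "duplicate protein")
})

test_that("mzTab loader maps assays to sample descriptions and handles null", {
  f <- withr::local_tempfile()
  writeLines(c(
    "MTD\tmzTab-version\t1.0.0",
    "MTD\tsample[1]-description\tliver_1",
    "MTD\tassay[1]-sample_ref\tsample[1]",
    "PRH\taccession\tdescription\tprotein_abundance_assay[1]\tprotein_abundance_assay[2]",
    "PRT\tP1\tfirst\t10.5\tnull",
    "PRT\tP2\tsecond\tnull\t3"), f)
  tab <- load_mztab(f)
  expect_equal(dim(tab$intensities), c(2, 2))
  # assay[1] resolves through sample_ref; assay[2] has no metadata entry
  expect_identical(tab$sample_names, c("liver_1", "assay[2]"))
  expect_true(is.na(tab$intensities["P1", "assay[2]"]))
  expect_true(is.na(tab$intensities["P2", "liver_1"]))

  writeLines(c("MTD\tmzTab-version\t1.0.0",
               "PRH\taccession\tprotein_abundance_assay[1]",
               "PRT\tP1\t1\textra_field"), f)
  expect_error(load_mztab(f), "column-count mismatch")

  writeLines(c("MTD\tmzTab-version\t1.0.0",
               "PRH\taccession\topt_something", "PRT\tP1\tx"), f)
  expect_error(load_mztab(f), "generic loader")

  writeLines(c("MTD\tmzTab-version\t1.0.0"), f)
  expect_error(load_mztab(f), "no PRT")
})

test_that("contaminant flagging fires on markers, prefixes and extra sets, idempotently", {
  f <- withr::local_tempfile()
  writeLines(c(
    paste("Majority protein IDs", "Potential contaminant", "Reverse",
          "LFQ intensity A", sep = "\t"),
    "P1\t\t\t10", "CON__P2\t\t\t11", "P3\t+\t\t12", "P4\t\t+\t13",
    "P5;CON__P9\t\t\t14", "P6\t\t\t15"), f)
  tab <- load_table(f, "maxquant")
  expect_false(any(tab$contaminant))
  flagged <- flag_contaminants(tab)
  expect_identical(unname(flagged$contaminant),
                   c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  # input not modified; repeated application is a fixed point
  expect_false(any(tab$contaminant))
  expect_identical(flag_contaminants(flagged)$contaminant,
                   flagged$contaminant)
  # extra accessions add flags on top of the dialect rules
  extra <- flag_contaminants(tab, extra_accessions = c("P1", "P6", "NOPE"))
  expect_identical(unname(extra$contaminant), rep(TRUE, 6))

  # on a clean table, n extra accessions set exactly n flags
  clean <- raw_protein_table(paste0("Q", 1:5),
                             matrix(1:10, 5, 2), c("A", "B"))
  hit <- flag_contaminants(clean, extra_accessions = c("Q2", "Q4"))
  expect_equal(sum(hit$contaminant), 2)
  expect_identical(unname(which(hit$contaminant)), c(2L, 4L))
})
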