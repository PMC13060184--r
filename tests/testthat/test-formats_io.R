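test_that("FASTA records are read with normalized sequences and stable order", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 target protein", "mklt", ">P2", "ACDE", "FGHI"), path)
  recs <- read_fasta(path)
  expect_equal(recs$accession, c("P1", "P2"))
  expect_equal(recs$sequence, c("MKLT", "ACDEFGHI"))
  expect_equal(recs$description[1], "target protein")
})

test_that("FASTA reader rejects empty files and illegal residues", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty))
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MK1T"), bad)
  expect_error(read_fasta(bad), "illegal character")
})

test_that("FASTA writing round-trips through the reader", {
  recs <- data.frame(accession = c("A1", "B2"),
                     description = c("first", ""),
                     sequence = c(strrep("MKLTSAY", 20), "ACDEFG"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  expect_equal(read_fasta(path), recs)
})

test_that("modification strings parse per the grammar and round-trip", {
  mods <- parse_modification_string("S3(Phospho,99.1); M5(Oxidation)")
  expect_equal(mods$residue_letter, c("S", "M"))
  expect_equal(mods$peptide_position, c(3L, 5L))
  expect_equal(mods$mod_name, c("Phospho", "Oxidation"))
  expect_equal(mods$confidence, c(99.1, NA))

  expect_equal(nrow(parse_modification_string("")), 0L)
  # boundary confidence is retained verbatim; filtering happens downstream
  expect_equal(parse_modification_string("T1(Phospho,75.0)")$confidence, 75)

  for (text in c("S3(Phospho,99.1); M5(Oxidation)", "T1(Phospho,75)", "")) {
    expect_equal(serialize_modifications(parse_modification_string(text)), text,
                 ignore_attr = TRUE)
  }
  expect_error(parse_modification_string("S3[Phospho]"), "malformed")
  expect_error(parse_modification_string("S3(Phospho,120)"))
})

test_that("PSM tables are validated against the design and FDR-filtered", {
  design <- tiny_design()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(tiny_psm_table(), path)
  psms <- read_psm_table(path, design)
  # the 0.02-FDR row is dropped and counted; NA FDR rows are kept
  expect_equal(nrow(psms), 3L)
  expect_equal(attr(psms, "n_fdr_filtered"), 1L)
  expect_equal(psms$psm_id, 1:3)

  relaxed <- read_psm_table(path, design, fdr_threshold = 0.05)
  expect_equal(nrow(relaxed), 4L)
  # raising the threshold never removes a previously retained row
  expect_true(all(psms$sample_id %in% relaxed$sample_id))
})

test_that("PSM validation reports bad rows precisely", {
  design <- tiny_design()
  bad_cond <- tiny_psm_table()
  bad_cond$condition[2] <- "latrunculin"
  expect_error(validate_psm_table(bad_cond, design), "unknown condition")

  bad_rep <- tiny_psm_table()
  bad_rep$replicate[1] <- 9L
  expect_error(validate_psm_table(bad_rep, design), "replicate")

  bad_pos <- tiny_psm_table()
  bad_pos$mods[1] <- "S9(Phospho,90)"
  expect_error(validate_psm_table(bad_pos, design), "outside peptide")

  bad_letter <- tiny_psm_table()
  bad_letter$mods[1] <- "T3(Phospho,90)"
  expect_error(validate_psm_table(bad_letter, design), "does not match")
})

test_that("report tables are written deterministically and guard overwrites", {
  design <- tiny_design()
  psms <- validate_psm_table(tiny_psm_table(), design)
  protein <- data.frame(accession = "P1", description = "",
                        sequence = "AAELSSPKMTIDEKAA")
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_pipeline(psms, protein, design, out_dir = out1)
  run_pipeline(psms, protein, design, out_dir = out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  expect_error(run_pipeline(psms, protein, design, out_dir = out1),
               "overwrite")
  # empty site list still yields a header-only sites.tsv
  none <- psms[psms$mods == "", , drop = FALSE]
  none$psm_id <- NULL
  out3 <- withr::local_tempdir()
  run_pipeline(none, protein, design, out_dir = out3)
  expect_equal(length(readLines(file.path(out3, "sites.tsv"))), 1L)
})
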