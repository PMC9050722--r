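test_that("read_gct parses a minimal well-formed file", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "1\t1", "Name\tDescription\tS1", "T1\tna\t0.0"), path)
  em <- read_gct(path)
  expect_equal(dim(em), c(1L, 1L))
  expect_identical(rownames(em$tpm), "T1")
  expect_identical(colnames(em$tpm), "S1")
  expect_equal(em$tpm[1, 1], 0)
})

test_that("GCT write/read round trip preserves values, order and bytes", {
  set.seed(11)
  tpm <- named_mat(matrix(round(runif(12, 0, 1000), 3), 3, 4), "ENST", "GTEX.S")
  em <- expression_matrix(tpm, description = paste0("desc", 1:3))
  f1 <- withr::local_tempfile(fileext = ".gct")
  write_gct(em, f1)
  back <- read_gct(f1)
  expect_identical(rownames(back$tpm), rownames(tpm))
  expect_identical(colnames(back$tpm), colnames(tpm))
  expect_equal(back$tpm, tpm, tolerance = 1e-12)
  expect_identical(unname(back$description), paste0("desc", 1:3))
  # writing what was read reproduces the canonical file byte for byte
  f2 <- withr::local_tempfile(fileext = ".gct")
  write_gct(back, f2)
  expect_identical(readLines(f2), readLines(f1))
})

test_that("read_gct rejects malformed files with specific errors", {
  bad_version <- withr::local_tempfile()
  writeLines(c("#2.0", "1\t1", "Name\tS1", "T1\t1"), bad_version)
  expect_error(read_gct(bad_version), class = "txrep_format_error")

  wrong_dims <- withr::local_tempfile()
  writeLines(
    c("#1.2", "5\t1", "Name\tDescription\tS1",
      paste0("T", 1:4, "\tna\t1", collapse = "\n")),
    wrong_dims
  )
  expect_error(read_gct(wrong_dims), class = "txrep_dimension_error")

  non_numeric <- withr::local_tempfile()
  writeLines(c("#1.2", "2\t2", "Name\tDescription\tS1\tS2",
               "T1\tna\t1.5\t2.5", "T2\tna\toops\t3"), non_numeric)
  err <- expect_error(read_gct(non_numeric), class = "txrep_value_error")
  expect_match(conditionMessage(err), "T2")
  expect_match(conditionMessage(err), "S1")
})

test_that("NA cells are rejected unless na_as_zero is opted in", {
  path <- withr::local_tempfile()
  writeLines(c("#1.2", "1\t2", "Name\tDescription\tS1\tS2", "T1\tna\t\t4"), path)
  expect_error(read_gct(path), class = "txrep_value_error")
  em <- suppressMessages(read_gct(path, na_as_zero = TRUE))
  expect_equal(unname(em$tpm[1, ]), c(0, 4))
})

test_that("read_gct can strip transcript version suffixes", {
  path <- withr::local_tempfile()
  writeLines(c("#1.2", "1\t1", "Name\tDescription\tS1", "ENST1.7\tna\t2"), path)
  expect_identical(rownames(read_gct(path)$tpm), "ENST1.7")
  expect_identical(rownames(read_gct(path, strip_versions = TRUE)$tpm), "ENST1")
})

test_that("sample attributes parse, ignore extra columns, and catch conflicts", {
  path <- withr::local_tempfile()
  writeLines(c(
    "SAMPID\tSMATSSCR\tSMTSD\tSMNABTCH\tSMGEBTCH",
    "S1\t1\tliver\tb1\tg1",
    "S2\t2\ttestis\tb2\tg2"
  ), path)
  st <- read_sample_attributes(path)
  expect_identical(st, c(S1 = "liver", S2 = "testis"))

  conflict <- withr::local_tempfile()
  writeLines(c("SAMPID\tSMTSD", "S1\tliver", "S1\tlung"), conflict)
  expect_error(read_sample_attributes(conflict), class = "txrep_conflict_error")

  # exact duplicate rows are tolerated
  dup <- withr::local_tempfile()
  writeLines(c("SAMPID\tSMTSD", "S1\tliver", "S1\tliver"), dup)
  expect_identical(read_sample_attributes(dup), c(S1 = "liver"))

  missing_col <- withr::local_tempfile()
  writeLines(c("SAMPID\tOTHER", "S1\tx"), missing_col)
  expect_error(read_sample_attributes(missing_col), class = "txrep_schema_error")

  empty_tissue <- withr::local_tempfile()
  writeLines(c("SAMPID\tSMTSD", "S1\t"), empty_tissue)
  expect_error(read_sample_attributes(empty_tissue), class = "txrep_value_error")
})

test_that("attach_sample_tissue drops unlabelled samples with a warning", {
  tpm <- named_mat(matrix(1:6, 2, 3), "T", "S")
  em <- expression_matrix(tpm)
  st <- c(S01 = "liver", S02 = "lung", S99 = "brain")
  expect_warning(
    joined <- suppressMessages(attach_sample_tissue(em, st)),
    "dropping 1 sample"
  )
  expect_identical(colnames(joined$tpm), c("S01", "S02"))
  expect_identical(unname(joined$sample_tissue), c("liver", "lung"))
})

test_that("annotation TSV round-trips and validates its invariants", {
  ann <- simple_annotation(
    c("T1", "T2", "T3"), c("G1", "G1", "G2"),
    transcript_length = c(1000L, 2000L, 500L),
    orf_length = c(300L, 0L, 450L),
    transcript_biotype = c("protein_coding", "retained_intron", "protein_coding")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, path)
  back <- read_annotation_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))

  expect_error(
    simple_annotation("T1", "G1", transcript_length = 100L, orf_length = 200L),
    class = "txrep_annotation_error"
  )
  expect_error(
    simple_annotation(c("T1", "T1"), "G1"),
    class = "txrep_annotation_error"
  )
  expect_error(
    annotation_table(data.frame(
      transcript_id = c("T1", "T2"), gene_id = "G1",
      gene_name = c("A", "B"), gene_biotype = "protein_coding",
      transcript_biotype = "protein_coding",
      transcript_length = 100L, orf_length = 0L
    )),
    class = "txrep_annotation_error"
  )
})

write_gtf_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gtf_line <- function(type, start, end, gene = "G1", tx = "TX1",
                     gtype = "protein_coding", ttype = "protein_coding") {
  sprintf(
    'chr1\ttest\t%s\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s_name"; gene_type "%s"; transcript_type "%s";',
    type, start, end, gene, tx, gene, gtype, ttype
  )
}

test_that("GTF-derived lengths follow the 1-based inclusive convention", {
  path <- write_gtf_fixture(c(
    gtf_line("exon", 1, 100), gtf_line("exon", 201, 250),
    gtf_line("CDS", 10, 99), gtf_line("stop_codon", 100, 102),
    gtf_line("exon", 300, 399, tx = "TX2", ttype = "processed_transcript")
  ))
  ann <- read_annotation_gtf(path)
  expect_equal(ann$transcript_length[ann$transcript_id == "TX1"], 150L)
  expect_equal(ann$orf_length[ann$transcript_id == "TX1"], 93L)
  # non-coding transcript: no CDS -> ORF length 0
  expect_equal(ann$orf_length[ann$transcript_id == "TX2"], 0L)
  expect_true(all(ann$orf_length <= ann$transcript_length))
})

test_that("GTF with CDS but no exon for a transcript is rejected", {
  path <- write_gtf_fixture(c(
    gtf_line("exon", 1, 100),
    gtf_line("CDS", 10, 60, tx = "TX_ORPHAN")
  ))
  expect_error(read_annotation_gtf(path), class = "txrep_annotation_error")
})

test_that("simulated studies survive a full write/read cycle", {
  sim <- simulate_expression(small_sim_config())
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  em <- read_gct(paths[["gct"]])
  em <- attach_sample_tissue(em, read_sample_attributes(paths[["sample_attributes"]]))
  expect_identical(rownames(em$tpm), rownames(sim$expression$tpm))
  expect_identical(colnames(em$tpm), colnames(sim$expression$tpm))
  expect_equal(em$tpm, sim$expression$tpm, tolerance = 1e-12)
  expect_identical(em$sample_tissue, sim$expression$sample_tissue)
  ann <- read_annotation_tsv(paths[["annotation"]])
  expect_equal(as.data.frame(ann), as.data.frame(sim$annotation))
})
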