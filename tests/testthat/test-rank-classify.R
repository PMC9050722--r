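test_that("filter_protein_coding keeps all isoforms of coding genes only", {
  tpm <- named_mat(matrix(1, 4, 2), "T", "S")
  ann <- annotation_table(data.frame(
    transcript_id = paste0("T", sprintf("%03d", 1:4)),
    gene_id = c("G1", "G2", "G1", "G3"),
    gene_name = c("A", "B", "A", "C"),
    gene_biotype = c("protein_coding", "lincRNA", "protein_coding", "protein_coding"),
    # a retained_intron isoform of a coding gene stays in
    transcript_biotype = c("protein_coding", "lincRNA", "retained_intron", "protein_coding"),
    transcript_length = 1000L, orf_length = 0L
  ))
  em <- filter_protein_coding(make_em(tpm), ann)
  expect_identical(rownames(em$tpm), c("T001", "T003", "T004"))
})

test_that("all-noncoding input yields an empty matrix with a warning", {
  tpm <- named_mat(matrix(1, 2, 2), "T", "S")
  ann <- simple_annotation(c("T001", "T002"), "G1", gene_biotype = "lincRNA")
  expect_warning(em <- filter_protein_coding(make_em(tpm), ann), "no transcripts")
  expect_equal(nrow(em$tpm), 0L)
})

test_that("drop_unexpressed removes only all-zero transcripts", {
  tpm <- named_mat(matrix(0, 3, 10), "T", "S")
  tpm[2, 4] <- 0.01  # a single positive value counts as expressed
  tpm[3, ] <- 1
  em <- suppressMessages(drop_unexpressed(make_em(tpm)))
  expect_identical(rownames(em$tpm), c("T002", "T003"))
  expect_equal(attr(em, "n_removed"), 1L)
})

test_that("within-gene ranks follow expression with ORF/length/id tie-breaks", {
  ann <- simple_annotation(
    c("Ta", "Tb", "Tc", "Td", "Te"),
    c("G1", "G1", "G2", "G2", "G3"),
    orf_length = c(300L, 150L, 300L, 300L, 0L),
    transcript_length = c(1000L, 1000L, 1000L, 2000L, 500L)
  )
  m <- c(Ta = 5, Tb = 5, Tc = 5, Td = 5, Te = 2)
  r <- rank_transcripts(m, ann)
  # equal TPM: longer ORF wins
  expect_equal(unname(r[c("Ta", "Tb")]), c(1L, 2L))
  # equal TPM and ORF: longer transcript wins
  expect_equal(unname(r[c("Tc", "Td")]), c(2L, 1L))
  # single-transcript gene
  expect_equal(unname(r["Te"]), 1L)
  # full tie falls back to transcript id ascending
  ann2 <- simple_annotation(c("TX2", "TX1"), "G1")
  r2 <- rank_transcripts(c(TX2 = 1, TX1 = 1), ann2)
  expect_equal(r2, c(TX2 = 2L, TX1 = 1L))
})

test_that("ranks match a brute-force comparator and form permutations", {
  set.seed(23)
  sim <- simulate_expression(small_sim_config(n_genes = 30L))
  tm <- tissue_means(sim$expression)
  m <- overall_mean(tm)
  # force some expression ties to exercise tie-breaking
  m[1:6] <- 5
  r <- rank_transcripts(m, sim$annotation)
  expect_identical(r, oracle_ranks(m, sim$annotation))
  gene <- sim$annotation$gene_id[match(names(m), sim$annotation$transcript_id)]
  for (ranks in split(unname(r), gene)) {
    expect_identical(sort(ranks), seq_along(ranks))
  }
})

test_that("z-scores match closed forms", {
  # constant vector: sigma = 0 convention gives z = 0 everywhere
  const <- make_tm(named_mat(matrix(4, 1, 54)))
  expect_true(all(zscores(const)$z == 0))

  # one-hot over 54 tissues: z_hot = sqrt(53), z_cold = -1/sqrt(53)
  onehot <- zscores(hot_tm(54, hot = 1, a = 7))
  expect_equal(unname(onehot$z[1, 1]), sqrt(53), tolerance = 1e-12)
  expect_equal(unname(onehot$z[1, 2]), -1 / sqrt(53), tolerance = 1e-12)

  # two-hot equal: z_hot = sqrt(52/2) ~ 5.099
  twohot <- zscores(hot_tm(54, hot = 2, a = 7))
  expect_equal(unname(twohot$z[1, 1:2]), rep(sqrt(26), 2), tolerance = 1e-12)

  # sample-SD mode scales by sqrt(n/(n-1))
  z_samp <- zscores(hot_tm(54, hot = 1, a = 7), sd_mode = "sample")
  expect_equal(unname(z_samp$z[1, 1]), sqrt(53) * sqrt(53 / 54), tolerance = 1e-12)

  expect_error(zscores(make_tm(named_mat(matrix(1, 2, 1)))), class = "txrep_config_error")
})

test_that("z-scores agree with the loop oracle and normalize exactly", {
  set.seed(31)
  for (mode in c("population", "sample")) {
    v <- named_mat(matrix(rlnorm(25 * 54, 1, 1.2), 25, 54))
    zs <- zscores(make_tm(v), sd_mode = mode)
    expect_equal(zs$z, oracle_zscores(v, mode == "population"), tolerance = 1e-12)
    expect_true(all(abs(rowSums(zs$z)) < 1e-9))
    target <- if (mode == "population") 54 else 53
    expect_true(all(abs(rowSums(zs$z^2) - target) < 1e-9))
  }
})

test_that("classification uses an inclusive cutoff and counts tissues", {
  z <- rbind(
    TXa = c(3, 2.999, -1),
    TXb = c(0, 0, 0),
    TXc = c(5, 4, 3)
  )
  colnames(z) <- c("liver", "lung", "testis")
  cls <- classify_representative(z, tau = 3)
  expect_identical(cls$representative$TXa, "liver")  # z = 3 exactly is in
  expect_identical(cls$representative$TXb, character(0))
  expect_equal(unname(cls$category), c(1L, 0L, 3L))
})

test_that("CV has the stated closed forms and scale invariance", {
  const <- make_tm(named_mat(matrix(5, 1, 54)))
  expect_equal(unname(coefficient_of_variation(const)), 0)

  onehot <- hot_tm(54, hot = 1, a = 3)
  expect_equal(unname(coefficient_of_variation(onehot)), sqrt(53), tolerance = 1e-12)

  set.seed(3)
  v <- named_mat(matrix(rlnorm(54), 1, 54))
  expect_equal(
    coefficient_of_variation(make_tm(v)),
    coefficient_of_variation(make_tm(v * 250)),
    tolerance = 1e-12
  )
  # mu = 0 convention
  zero <- make_tm(named_mat(matrix(0, 1, 3)))
  expect_equal(unname(coefficient_of_variation(zero)), 0)
})

test_that("classification is invariant under per-transcript rescaling", {
  set.seed(41)
  v <- named_mat(matrix(rlnorm(10 * 54, 0, 2), 10, 54))
  scale <- runif(10, 0.01, 100)
  a <- classify_representative(zscores(make_tm(v))$z)
  b <- classify_representative(zscores(make_tm(v * scale))$z)
  expect_identical(a$representative, b$representative)
  expect_identical(a$category, b$category)
})

test_that("tail_probability is the one-sided normal tail", {
  expect_equal(tail_probability(0), 0.5)
  expect_equal(tail_probability(-Inf), 1)
  expect_equal(tail_probability(Inf), 0)
  expect_equal(tail_probability(1.96), 0.025, tolerance = 1e-3)
})

test_that("transcript_profiles assembles consistent per-transcript rows", {
  sim <- simulate_expression(small_sim_config())
  em <- suppressMessages(drop_unexpressed(
    suppressWarnings(filter_protein_coding(sim$expression, sim$annotation))
  ))
  tm <- tissue_means(em)
  prof <- transcript_profiles(tm, sim$annotation)
  expect_identical(prof$transcript_id, rownames(tm$values))
  expect_equal(lengths(prof$representative_tissues), prof$category)
  expect_equal(prof$cv, ifelse(prof$mu > 0, prof$sigma / prof$mu, 0))
  # rank-1 dominance: within each gene the rank-1 transcript has max mean
  for (rows in split(seq_len(nrow(prof)), prof$gene_id)) {
    top <- rows[prof$rank[rows] == 1L]
    expect_true(prof$overall_mean_tpm[top] >= max(prof$overall_mean_tpm[rows]))
  }
  # profile TSV round trip of the flat columns
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(prof, path, include_z = TRUE)
  flat <- utils::read.delim(path)
  expect_equal(nrow(flat), nrow(prof))
  expect_true(all(paste0("z.", colnames(attr(prof, "z"))) %in% names(flat)))
})
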