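#' Configuration for the synthetic expression generator
#'
#' Describes a GTEx-shaped study: multi-isoform protein-coding genes
#' (isoform counts `1 + Poisson(mean_isoforms_per_gene - 1)`), many tissue
#' subtypes with unequal donor counts, log-normal per-transcript baselines
#' and per-donor multiplicative log-normal noise. A configurable fraction
#' of transcripts is housekeeping-like (uniform high baseline across all
#' tissues), a fraction is tissue-specific (baseline multiplied by
#' `fold_change` in 1-4 planted tissues), and the rest is background.
#' Multi-tissue plantings use consecutive tissue blocks to emulate related
#' subregions (adipose, brain, skin subtypes).
#'
#' @param n_genes Number of genes.
#' @param mean_isoforms_per_gene Mean isoforms per gene (default 7).
#' @param n_tissues Number of tissue subtypes (default 54).
#' @param donors_per_tissue_range Integer interval the per-tissue donor
#'   counts are drawn from uniformly (default `c(20, 200)`).
#' @param frac_housekeeping Fraction of transcripts with a uniform high
#'   baseline (default 0.2).
#' @param frac_tissue_specific Fraction of transcripts with a planted
#'   tissue signal (default 0.3). Must satisfy
#'   `frac_housekeeping + frac_tissue_specific <= 1`.
#' @param planted_tissue_count_weights Sampling weights for the number of
#'   planted tissues 1-4 (default heavily favouring single-tissue signals,
#'   mirroring the empirical predominance of the one-tissue class).
#' @param fold_change Multiplicative fold applied to the baseline in
#'   planted tissues (default 100).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   background/tissue-specific baseline TPM (defaults `log(5)`, 1).
#' @param hk_log_mean,hk_log_sd Log-normal parameters of the housekeeping
#'   baseline (defaults `log(90)`, 0.5 — broadly expressed transcripts sit
#'   near ~90 TPM).
#' @param noise_log_sd Donor-level multiplicative log-normal noise SD on
#'   the log scale (default 0.5); 0 gives noise-free data.
#' @param frac_noncoding_genes Fraction of genes given a non-coding biotype
#'   to exercise the protein-coding filter (default 0.05).
#' @param seed Integer RNG seed; identical configurations give identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       mean_isoforms_per_gene = 7,
                       n_tissues = 54L,
                       donors_per_tissue_range = c(20L, 200L),
                       frac_housekeeping = 0.2,
                       frac_tissue_specific = 0.3,
                       planted_tissue_count_weights = c(`1` = 0.66, `2` = 0.30, `3` = 0.035, `4` = 0.005),
                       fold_change = 100,
                       baseline_log_mean = log(5),
                       baseline_log_sd = 1,
                       hk_log_mean = log(90),
                       hk_log_sd = 0.5,
                       noise_log_sd = 0.5,
                       frac_noncoding_genes = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    mean_isoforms_per_gene = mean_isoforms_per_gene,
    n_tissues = as.integer(n_tissues),
    donors_per_tissue_range = as.integer(donors_per_tissue_range),
    frac_housekeeping = frac_housekeeping,
    frac_tissue_specific = frac_tissue_specific,
    planted_tissue_count_weights = planted_tissue_count_weights,
    fold_change = fold_change,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    hk_log_mean = hk_log_mean,
    hk_log_sd = hk_log_sd,
    noise_log_sd = noise_log_sd,
    frac_noncoding_genes = frac_noncoding_genes,
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L || cfg$n_tissues < 1L) {
    txrep_error("txrep_config_error", "n_genes and n_tissues must be positive")
  }
  if (cfg$mean_isoforms_per_gene < 1) {
    txrep_error("txrep_config_error", "mean_isoforms_per_gene must be >= 1")
  }
  if (length(cfg$donors_per_tissue_range) != 2L ||
      cfg$donors_per_tissue_range[1L] < 1L ||
      diff(cfg$donors_per_tissue_range) < 0L) {
    txrep_error("txrep_config_error", "donors_per_tissue_range must be a valid positive interval")
  }
  fr <- c(cfg$frac_housekeeping, cfg$frac_tissue_specific, cfg$frac_noncoding_genes)
  if (any(fr < 0) || any(fr > 1) ||
      cfg$frac_housekeeping + cfg$frac_tissue_specific > 1) {
    txrep_error("txrep_config_error", "fractions must lie in [0,1] with housekeeping + tissue_specific <= 1")
  }
  if (cfg$fold_change <= 0 || cfg$baseline_log_sd < 0 || cfg$hk_log_sd < 0 ||
      cfg$noise_log_sd < 0) {
    txrep_error("txrep_config_error", "scale parameters must be positive")
  }
  wk <- cfg$planted_tissue_count_weights
  if (length(wk) < 1L || length(wk) > 4L || any(wk < 0) || sum(wk) <= 0) {
    txrep_error("txrep_config_error", "planted_tissue_count_weights must be 1-4 non-negative weights")
  }
  if (max(seq_along(wk)[wk > 0]) > cfg$n_tissues) {
    txrep_error("txrep_config_error", "cannot plant more tissues than exist")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a GTEx-shaped transcript expression study with known truth
#'
#' Draws a transcript x sample TPM matrix, matching annotation and tissue
#' assignment, plus per-transcript ground-truth labels, from a
#' [sim_config()]. Expected TPM of transcript i in tissue j is
#' `baseline_i * fold` in planted tissues and `baseline_i` elsewhere; each
#' donor sample observes the expectation times `LogNormal(0, noise_log_sd)`
#' noise. All randomness derives from the configuration seed through R's
#' default Mersenne-Twister generator, restored afterwards, so identical
#' configurations give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `txrep_simulation` with elements `expression`
#'   (an [expression_matrix()] with tissue assignment), `annotation`
#'   (an [annotation_table()]), `truth` (data frame: `transcript_id`,
#'   `gene_id`, `label` in housekeeping/tissue_specific/background,
#'   comma-joined `planted_tissues`, `fold`, `baseline`) and `config`.
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_expression_impl(config))
}

simulate_expression_impl <- function(cfg) {
  gene_ids <- sprintf("SIMG%05d", seq_len(cfg$n_genes))
  gene_names <- sprintf("Gene%d", seq_len(cfg$n_genes))
  noncoding <- runif(cfg$n_genes) < cfg$frac_noncoding_genes
  gene_biotype <- ifelse(noncoding, "lincRNA", "protein_coding")

  n_iso <- 1L + rpois(cfg$n_genes, cfg$mean_isoforms_per_gene - 1)
  gene_idx <- rep.int(seq_len(cfg$n_genes), n_iso)
  n_tx <- length(gene_idx)
  tx_ids <- sprintf("SIMT%06d.1", seq_len(n_tx))

  # truth labels; transcripts of non-coding genes are background (they are
  # removed by the biotype filter and carry no planted signal)
  label <- sample(
    c("housekeeping", "tissue_specific", "background"),
    n_tx, replace = TRUE,
    prob = c(
      cfg$frac_housekeeping, cfg$frac_tissue_specific,
      1 - cfg$frac_housekeeping - cfg$frac_tissue_specific
    )
  )
  label[noncoding[gene_idx]] <- "background"

  baseline <- ifelse(
    label == "housekeeping",
    rlnorm(n_tx, cfg$hk_log_mean, cfg$hk_log_sd),
    rlnorm(n_tx, cfg$baseline_log_mean, cfg$baseline_log_sd)
  )

  tissues <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))
  wk <- cfg$planted_tissue_count_weights
  planted <- vector("list", n_tx)
  planted[] <- list(character(0))
  for (i in which(label == "tissue_specific")) {
    k <- sample.int(length(wk), 1L, prob = wk)
    start <- sample.int(cfg$n_tissues - k + 1L, 1L)
    planted[[i]] <- tissues[start:(start + k - 1L)]  # consecutive block: related subregions
  }

  donors <- sample(
    seq.int(cfg$donors_per_tissue_range[1L], cfg$donors_per_tissue_range[2L]),
    cfg$n_tissues, replace = TRUE
  )
  tissue_of_sample <- rep.int(seq_len(cfg$n_tissues), donors)
  sample_ids <- unlist(lapply(seq_len(cfg$n_tissues), function(j) {
    sprintf("%s.D%03d", tissues[j], seq_len(donors[j]))
  }), use.names = FALSE)
  n_samp <- length(sample_ids)

  expected <- matrix(baseline, nrow = n_tx, ncol = cfg$n_tissues,
                     dimnames = list(tx_ids, tissues))
  for (i in which(label == "tissue_specific")) {
    expected[i, planted[[i]]] <- expected[i, planted[[i]]] * cfg$fold_change
  }
  tpm <- expected[, tissue_of_sample, drop = FALSE]
  if (cfg$noise_log_sd > 0) {
    tpm <- tpm * matrix(rlnorm(n_tx * n_samp, 0, cfg$noise_log_sd), n_tx, n_samp)
  }
  dimnames(tpm) <- list(tx_ids, sample_ids)

  tx_len <- pmax(200L, as.integer(round(rlnorm(n_tx, log(2500), 0.6))))
  coding_tx <- !noncoding[gene_idx] & runif(n_tx) < 0.75
  orf <- integer(n_tx)
  orf[coding_tx] <- pmin(
    tx_len[coding_tx],
    pmax(30L, as.integer(3L * floor(tx_len[coding_tx] * runif(sum(coding_tx), 0.2, 0.8) / 3)))
  )
  tb <- rep("protein_coding", n_tx)
  tb[!coding_tx] <- sample(
    c("retained_intron", "processed_transcript", "nonsense_mediated_decay"),
    sum(!coding_tx), replace = TRUE
  )
  tb[noncoding[gene_idx]] <- "lincRNA"

  annotation <- annotation_table(data.frame(
    transcript_id = tx_ids,
    gene_id = gene_ids[gene_idx],
    gene_name = gene_names[gene_idx],
    gene_biotype = gene_biotype[gene_idx],
    transcript_biotype = tb,
    transcript_length = tx_len,
    orf_length = orf,
    stringsAsFactors = FALSE
  ))
  truth <- data.frame(
    transcript_id = tx_ids,
    gene_id = gene_ids[gene_idx],
    label = label,
    planted_tissues = vapply(planted, paste, character(1), collapse = ","),
    fold = ifelse(label == "tissue_specific", cfg$fold_change, 1),
    baseline = baseline,
    stringsAsFactors = FALSE
  )
  expr <- expression_matrix(
    tpm,
    sample_tissue = stats::setNames(tissues[tissue_of_sample], sample_ids)
  )
  structure(
    list(expression = expr, annotation = annotation, truth = truth, config = cfg),
    class = "txrep_simulation"
  )
}

#' @export
print.txrep_simulation <- function(x, ...) {
  cat(sprintf(
    "<txrep_simulation> %d transcripts (%d genes) x %d samples, %d tissues, seed %d\n",
    nrow(x$expression$tpm), length(unique(x$annotation$gene_id)),
    ncol(x$expression$tpm), length(unique(x$expression$sample_tissue)),
    x$config$seed
  ))
  invisible(x)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits the GCT expression matrix, a SAMPID/SMTSD sample-attribute TSV,
#' the annotation TSV and the ground-truth TSV, so the reader path can be
#' exercised end-to-end on synthetic data.
#'
#' @param sim A `txrep_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "txrep_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gct = file.path(dir, "expression.gct"),
    sample_attributes = file.path(dir, "sample_attributes.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_gct(sim$expression, paths[["gct"]])
  data.table::fwrite(
    data.table::data.table(
      SAMPID = names(sim$expression$sample_tissue),
      SMTSD = unname(sim$expression$sample_tissue)
    ),
    paths[["sample_attributes"]], sep = "\t", quote = FALSE
  )
  write_annotation_tsv(sim$annotation, paths[["annotation"]])
  data.table::fwrite(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE)
  invisible(paths)
}

#' Recovery of planted truth by the classification pipeline
#'
#' Compares classified profiles against the generator's ground truth:
#' * sensitivity — fraction of tissue-specific transcripts that are
#'   representative (category >= 1) of at least one of their planted
#'   tissues;
#' * specificity — fraction of housekeeping transcripts classified as
#'   commonly expressed (category 0);
#' * set accuracy — fraction of tissue-specific transcripts whose
#'   representative set equals the planted set exactly.
#'
#' @param profiles A `transcript_profiles` data frame.
#' @param truth The `truth` data frame of a [simulate_expression()] result.
#' @return Named list: `sensitivity`, `specificity`, `set_accuracy`,
#'   `n_tissue_specific`, `n_housekeeping` (metrics are `NaN` when the
#'   corresponding truth class is absent from the profiles).
#' @export
recovery_metrics <- function(profiles, truth) {
  stopifnot(inherits(profiles, "transcript_profiles"))
  idx <- match(profiles$transcript_id, truth$transcript_id)
  if (anyNA(idx)) {
    bad <- profiles$transcript_id[is.na(idx)]
    txrep_error(
      "txrep_key_error",
      sprintf("profile transcript(s) missing from truth: %s", paste(head(bad, 5L), collapse = ", "))
    )
  }
  label <- truth$label[idx]
  planted <- strsplit(truth$planted_tissues[idx], ",", fixed = TRUE)
  planted[is.na(truth$planted_tissues[idx])] <- list(character(0))
  ts <- which(label == "tissue_specific")
  hk <- which(label == "housekeeping")
  hit <- vapply(ts, function(i) {
    profiles$category[i] >= 1L &&
      length(intersect(profiles$representative_tissues[[i]], planted[[i]])) > 0L
  }, logical(1))
  exact <- vapply(ts, function(i) {
    setequal(profiles$representative_tissues[[i]], planted[[i]])
  }, logical(1))
  list(
    sensitivity = mean(hit),
    specificity = mean(profiles$category[hk] == 0L),
    set_accuracy = mean(exact),
    n_tissue_specific = length(ts),
    n_housekeeping = length(hk)
  )
}
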