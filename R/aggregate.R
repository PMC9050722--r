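#' Collapse sample-level TPM to per-tissue means
#'
#' Averages TPM over all samples of each tissue subtype. Aggregating to the
#' tissue level first (rather than pooling donors) keeps tissues with few
#' donors on an equal footing with heavily sampled ones; the downstream
#' Z-score operates on this tissue-level vector. Tissue columns are ordered
#' lexicographically (C locale) so outputs are deterministic.
#'
#' @param x An [expression_matrix()] with `sample_tissue` attached.
#' @return A [tissue_matrix()] of per-tissue mean TPM with sample counts.
#' @export
tissue_means <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(x$sample_tissue)) {
    txrep_error("txrep_config_error", "expression matrix has no sample_tissue assignment")
  }
  tissues <- sort_c(unique(unname(x$sample_tissue)))
  grp <- factor(x$sample_tissue[colnames(x$tpm)], levels = tissues)
  counts <- table(grp)
  if (any(counts == 0L)) {
    txrep_error(
      "txrep_config_error",
      sprintf("tissue label(s) with zero samples: %s", paste(names(counts)[counts == 0L], collapse = ", "))
    )
  }
  sums <- t(rowsum(t(x$tpm), group = grp, reorder = FALSE))
  values <- sweep(sums, 2L, as.numeric(counts[colnames(sums)]), "/")
  values <- values[, tissues, drop = FALSE]
  tissue_matrix(values, stats::setNames(as.integer(counts[tissues]), tissues))
}

#' Per-transcript overall mean TPM
#'
#' By default the unweighted mean of the tissue means, so every tissue
#' subtype contributes equally regardless of donor count; set
#' `donor_weighted = TRUE` to weight tissues by their sample counts
#' (equivalent to a grand mean over all samples) for sensitivity analysis.
#'
#' @param x A [tissue_matrix()].
#' @param donor_weighted Weight tissues by sample count. Default `FALSE`.
#' @return Named numeric vector of overall mean TPM per transcript.
#' @export
overall_mean <- function(x, donor_weighted = FALSE) {
  stopifnot(inherits(x, "tissue_matrix"))
  if (ncol(x$values) < 1L) {
    txrep_error("txrep_config_error", "need at least one tissue")
  }
  if (donor_weighted) {
    w <- as.numeric(x$n_samples)
    drop(x$values %*% w) / sum(w)
  } else {
    rowMeans(x$values)
  }
}

#' Gene-level TPM and per-transcript expression shares
#'
#' Gene TPM in a tissue is the sum of the gene's transcript tissue-mean
#' TPMs (the RSEM-consistent convention). The share (`Rank TPM%`) of
#' transcript i in tissue j is `100 * x_ij / gene_tpm`; when a gene has
#' zero TPM in a tissue all its shares are defined as 0.
#'
#' @param x A [tissue_matrix()].
#' @param annotation An [annotation_table()] covering every transcript of `x`.
#' @return A list of class `gene_tissue_matrix` with elements `gene_tpm`
#'   (gene x tissue matrix), `shares` (transcript x tissue percentage
#'   matrix) and `gene_of` (named map transcript -> gene).
#' @export
gene_tpm_and_shares <- function(x, annotation) {
  stopifnot(inherits(x, "tissue_matrix"), inherits(annotation, "annotation_table"))
  gene_of <- stats::setNames(annotation$gene_id, annotation$transcript_id)[rownames(x$values)]
  if (anyNA(gene_of)) {
    bad <- rownames(x$values)[is.na(gene_of)]
    txrep_error(
      "txrep_key_error",
      sprintf("transcript(s) missing from annotation: %s", paste(head(bad, 5L), collapse = ", "))
    )
  }
  names(gene_of) <- rownames(x$values)
  gene_tpm <- rowsum(x$values, group = gene_of, reorder = FALSE)
  gene_tpm <- gene_tpm[sort_c(rownames(gene_tpm)), , drop = FALSE]
  denom <- gene_tpm[gene_of, , drop = FALSE]
  shares <- ifelse(denom > 0, 100 * x$values / denom, 0)
  dimnames(shares) <- dimnames(x$values)
  structure(
    list(gene_tpm = gene_tpm, shares = shares, gene_of = gene_of),
    class = "gene_tissue_matrix"
  )
}
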