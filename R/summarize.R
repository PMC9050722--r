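profile_basis_tpm <- function(profiles, tpm_basis) {
  if (tpm_basis == "overall_mean") {
    return(profiles$overall_mean_tpm)
  }
  # max tissue-mean TPM over the representative tissues; commonly expressed
  # (category-0) transcripts have no representative tissue, so they fall
  # back to the overall mean
  tm <- attr(profiles, "tissue_matrix")
  if (is.null(tm)) {
    txrep_error("txrep_config_error", "tpm_basis = 'representative_max' needs the attached tissue matrix")
  }
  v <- tm$values[profiles$transcript_id, , drop = FALSE]
  out <- profiles$overall_mean_tpm
  has <- profiles$category >= 1L
  out[has] <- vapply(
    which(has),
    function(i) max(v[i, profiles$representative_tissues[[i]]]),
    numeric(1)
  )
  out
}

#' Tissue-count category table
#'
#' Cross-tabulates transcripts by tissue-count category (0 = commonly
#' expressed, 1-4 = representative in that many tissues, with an overflow
#' `>=5` row when present) against TPM thresholds, plus a totals row.
#' The percentage of the grand total passing each threshold is attached
#' as attribute `percent` and shown by `print()`.
#'
#' @param profiles A `transcript_profiles` data frame.
#' @param thresholds Numeric TPM thresholds, default `c(1, 10, 100)`.
#' @param tpm_basis Which TPM the thresholds apply to: `"overall_mean"`
#'   (default) or `"representative_max"` (maximum tissue-mean TPM over the
#'   transcript's representative tissues).
#' @return Data frame of class `category_table` with a `category` column
#'   (`"0"`..`"4"`, optionally `">=5"`, then `"total"`), `n_transcripts`,
#'   and one `n_tpm_ge_<t>` column per threshold.
#' @export
category_table <- function(profiles, thresholds = c(1, 10, 100),
                           tpm_basis = c("overall_mean", "representative_max")) {
  stopifnot(inherits(profiles, "transcript_profiles"))
  tpm_basis <- match.arg(tpm_basis)
  m <- profile_basis_tpm(profiles, tpm_basis)
  cat_label <- ifelse(profiles$category >= 5L, ">=5", as.character(profiles$category))
  labels <- as.character(0:4)
  if (any(cat_label == ">=5")) labels <- c(labels, ">=5")
  count_row <- function(sel) {
    c(sum(sel), vapply(thresholds, function(t) sum(sel & m >= t), numeric(1)))
  }
  rows <- t(vapply(labels, function(l) count_row(cat_label == l), numeric(1L + length(thresholds))))
  totals <- count_row(rep(TRUE, nrow(profiles)))
  tab <- as.data.frame(rbind(rows, total = totals))
  names(tab) <- c("n_transcripts", paste0("n_tpm_ge_", thresholds))
  tab <- cbind(category = c(labels, "total"), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  grand <- totals[1L]
  attr(tab, "percent") <- if (grand > 0) 100 * totals / grand else totals * 0
  attr(tab, "tpm_basis") <- tpm_basis
  class(tab) <- c("category_table", "data.frame")
  tab
}

#' @export
print.category_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  pct <- attr(x, "percent")
  cat(sprintf(
    "totals as %% of %d transcripts: %s (TPM basis: %s)\n",
    x$n_transcripts[x$category == "total"],
    paste(sprintf("%.1f%%", pct[-1L]), collapse = ", "),
    attr(x, "tpm_basis")
  ))
  invisible(x)
}

#' Per-tissue report of representative transcripts
#'
#' For every tissue: how many transcripts are representative of it, their
#' mean TPM, and the most expressed transcript/gene. A transcript
#' representative in k tissues contributes to k rows, so the counts sum to
#' the sum of categories. Tissues without any representative transcript
#' report a mean of 0 with `empty = TRUE` rather than NaN.
#'
#' @param profiles A `transcript_profiles` data frame.
#' @param tpm_basis `"overall_mean"` (default: mean of the transcripts'
#'   overall mean TPM) or `"in_tissue"` (mean of their tissue-mean TPM in
#'   that tissue).
#' @return Data frame with columns `tissue`, `n_transcripts`, `mean_tpm`,
#'   `empty`, `top_transcript_id`, `top_gene_id`, one row per tissue in
#'   deterministic order.
#' @export
tissue_report <- function(profiles, tpm_basis = c("overall_mean", "in_tissue")) {
  stopifnot(inherits(profiles, "transcript_profiles"))
  tpm_basis <- match.arg(tpm_basis)
  tm <- attr(profiles, "tissue_matrix")
  tissues <- colnames(attr(profiles, "z"))
  rows <- lapply(tissues, function(tis) {
    member <- vapply(
      profiles$representative_tissues,
      function(s) tis %in% s, logical(1)
    )
    n <- sum(member)
    if (n == 0L) {
      return(data.frame(
        tissue = tis, n_transcripts = 0L, mean_tpm = 0, empty = TRUE,
        top_transcript_id = NA_character_, top_gene_id = NA_character_,
        stringsAsFactors = FALSE
      ))
    }
    tpm <- if (tpm_basis == "in_tissue") {
      tm$values[profiles$transcript_id[member], tis]
    } else {
      profiles$overall_mean_tpm[member]
    }
    ids <- profiles$transcript_id[member]
    top <- ids[order_c(-tpm, ids)][1L]
    data.frame(
      tissue = tis, n_transcripts = n, mean_tpm = mean(tpm), empty = FALSE,
      top_transcript_id = top,
      top_gene_id = profiles$gene_id[match(top, profiles$transcript_id)],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-stratified summary
#'
#' For each within-gene rank r (1..`max_rank`): the number of transcripts
#' of that rank, how many are representative of at least one tissue, the
#' percentage, and the mean overall TPM per tissue-count category bucket
#' (0..4, with categories above 4 pooled into `4`+... bucket `ge5`).
#'
#' @param profiles A `transcript_profiles` data frame.
#' @param max_rank Largest rank row to report, default 10.
#' @return Data frame with one row per rank.
#' @export
rank_table <- function(profiles, max_rank = 10L) {
  stopifnot(inherits(profiles, "transcript_profiles"))
  buckets <- c("0", "1", "2", "3", "4", "ge5")
  bucket_of <- ifelse(profiles$category >= 5L, "ge5", as.character(profiles$category))
  rows <- lapply(seq_len(max_rank), function(r) {
    sel <- profiles$rank == r
    n_total <- sum(sel)
    n_rep <- sum(sel & profiles$category >= 1L)
    means <- vapply(buckets, function(b) {
      s <- sel & bucket_of == b
      if (any(s)) mean(profiles$overall_mean_tpm[s]) else NA_real_
    }, numeric(1))
    out <- data.frame(
      rank = r, n_total = n_total, n_representative = n_rep,
      pct_representative = if (n_total > 0) 100 * n_rep / n_total else NA_real_,
      stringsAsFactors = FALSE
    )
    out[paste0("mean_tpm_cat", buckets)] <- as.list(means)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect isoform switches across tissues
#'
#' Flags genes in which two (or more) transcripts are each representative
#' of at least one tissue but of *disjoint* tissue sets — the PCP2 pattern,
#' where one isoform dominates the cerebellum and another the testis.
#' A gene is flagged when any pair of its category >= 1 transcripts has
#' non-overlapping representative sets.
#'
#' @param profiles A `transcript_profiles` data frame.
#' @return Data frame listing, for every flagged gene, its category >= 1
#'   transcripts with their ranks and comma-joined representative tissue
#'   sets; zero rows when no gene qualifies.
#' @export
switch_events <- function(profiles) {
  stopifnot(inherits(profiles, "transcript_profiles"))
  empty <- data.frame(
    gene_id = character(0), gene_name = character(0),
    transcript_id = character(0), rank = integer(0),
    representative_tissues = character(0), stringsAsFactors = FALSE
  )
  rep_rows <- which(profiles$category >= 1L)
  if (length(rep_rows) < 2L) return(empty)
  by_gene <- split(rep_rows, profiles$gene_id[rep_rows])
  by_gene <- by_gene[vapply(by_gene, length, integer(1)) >= 2L]
  flagged <- names(by_gene)[vapply(by_gene, function(rows) {
    sets <- profiles$representative_tissues[rows]
    for (a in seq_along(sets)[-length(sets)]) {
      for (b in (a + 1L):length(sets)) {
        if (!length(intersect(sets[[a]], sets[[b]]))) return(TRUE)
      }
    }
    FALSE
  }, logical(1))]
  if (!length(flagged)) return(empty)
  rows <- sort(unlist(by_gene[sort_c(flagged)], use.names = FALSE))
  out <- data.frame(
    gene_id = profiles$gene_id[rows],
    gene_name = profiles$gene_name[rows],
    transcript_id = profiles$transcript_id[rows],
    rank = profiles$rank[rows],
    representative_tissues = vapply(
      profiles$representative_tissues[rows], paste, character(1), collapse = ","
    ),
    stringsAsFactors = FALSE
  )
  out <- out[order_c(out$gene_id, out$rank, out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Export the top genes representative of a tissue
#'
#' Selects transcripts of the requested rank that are representative of the
#' tissue, orders them by that tissue's mean TPM (descending, ties broken
#' by gene id ascending) and returns the top `n` — the input for external
#' enrichment tools.
#'
#' @param profiles A `transcript_profiles` data frame.
#' @param tissue Tissue label (must exist in the profiles' tissue set).
#' @param n Maximum number of genes, default 100.
#' @param rank_filter Within-gene rank to restrict to, default 1.
#' @param path Optional TSV output path.
#' @return Data frame with `gene_id`, `gene_name`, `transcript_id`,
#'   `tissue_tpm`, at most `n` rows.
#' @export
top_genes_export <- function(profiles, tissue, n = 100L, rank_filter = 1L, path = NULL) {
  stopifnot(inherits(profiles, "transcript_profiles"))
  tm <- attr(profiles, "tissue_matrix")
  if (!tissue %in% colnames(tm$values)) {
    txrep_error("txrep_key_error", sprintf("unknown tissue: %s", tissue))
  }
  sel <- profiles$rank == rank_filter & vapply(
    profiles$representative_tissues, function(s) tissue %in% s, logical(1)
  )
  ids <- profiles$transcript_id[sel]
  tpm <- tm$values[ids, tissue]
  ord <- order_c(-tpm, profiles$gene_id[sel])
  keep <- head(ord, n)
  out <- data.frame(
    gene_id = profiles$gene_id[sel][keep],
    gene_name = profiles$gene_name[sel][keep],
    transcript_id = ids[keep],
    tissue_tpm = as.numeric(tpm[keep]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(path)) {
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  }
  out
}
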