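# Fixtures built in code: tiny matrices with hand-checkable values, plus
# independent brute-force oracles kept deliberately loop-based so they share
# no code path with the vectorised implementation.

make_em <- function(tpm, tissues = NULL) {
  st <- if (!is.null(tissues)) stats::setNames(tissues, colnames(tpm)) else NULL
  expression_matrix(tpm, sample_tissue = st)
}

make_tm <- function(values, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- rep(1L, ncol(values))
  tissue_matrix(values, stats::setNames(as.integer(n_samples), colnames(values)))
}

# transcript x tissue matrix with named dims from a plain numeric matrix
named_mat <- function(values, prefix_row = "TX", prefix_col = "tissue_") {
  matrix(
    values, nrow = nrow(values), ncol = ncol(values),
    dimnames = list(
      sprintf("%s%03d", prefix_row, seq_len(nrow(values))),
      sprintf("%s%02d", prefix_col, seq_len(ncol(values)))
    )
  )
}

# one transcript whose tissue vector has value `a` in `hot` tissues and
# `b` elsewhere, over `n` tissues
hot_tm <- function(n = 54, hot = 1, a = 100, b = 0) {
  v <- matrix(b, nrow = 1, ncol = n, dimnames = list("TX1", sprintf("tissue_%02d", 1:n)))
  v[1, seq_len(hot)] <- a
  make_tm(v)
}

simple_annotation <- function(transcript_id, gene_id,
                              gene_biotype = "protein_coding",
                              transcript_biotype = "protein_coding",
                              transcript_length = 1000L, orf_length = 300L,
                              gene_name = NULL) {
  n <- length(transcript_id)
  if (is.null(gene_name)) gene_name <- paste0("name_", gene_id)
  annotation_table(data.frame(
    transcript_id = transcript_id,
    gene_id = rep_len(gene_id, n),
    gene_name = rep_len(gene_name, n),
    gene_biotype = rep_len(gene_biotype, n),
    transcript_biotype = rep_len(transcript_biotype, n),
    transcript_length = rep_len(transcript_length, n),
    orf_length = rep_len(orf_length, n),
    stringsAsFactors = FALSE
  ))
}

# independent per-row loop oracle for z-scores (explicit formula evaluation)
oracle_zscores <- function(values, population = TRUE) {
  z <- values * NA_real_
  for (i in seq_len(nrow(values))) {
    x <- values[i, ]
    n <- length(x)
    mu <- sum(x) / n
    ss <- 0
    for (j in seq_len(n)) ss <- ss + (x[j] - mu)^2
    sg <- sqrt(ss / if (population) n else (n - 1))
    z[i, ] <- if (sg > 0) (x - mu) / sg else 0
  }
  z
}

# brute-force group-by mean, one cell at a time
oracle_tissue_means <- function(tpm, tissue_of) {
  tissues <- sort(unique(tissue_of), method = "radix")
  out <- matrix(
    NA_real_, nrow(tpm), length(tissues),
    dimnames = list(rownames(tpm), tissues)
  )
  for (i in seq_len(nrow(tpm))) {
    for (t in tissues) {
      vals <- tpm[i, names(tissue_of)[tissue_of == t]]
      out[i, t] <- sum(vals) / length(vals)
    }
  }
  out
}

# brute-force within-gene rank comparator mirroring the stated sort key
oracle_ranks <- function(m, ann) {
  out <- stats::setNames(integer(length(m)), names(m))
  idx <- match(names(m), ann$transcript_id)
  for (g in unique(ann$gene_id[idx])) {
    ids <- names(m)[ann$gene_id[idx] == g]
    key <- function(id) {
      k <- match(id, ann$transcript_id)
      list(m = m[[id]], orf = ann$orf_length[k], len = ann$transcript_length[k], id = id)
    }
    better <- function(a, b) {
      ka <- key(a); kb <- key(b)
      if (ka$m != kb$m) return(ka$m > kb$m)
      if (ka$orf != kb$orf) return(ka$orf > kb$orf)
      if (ka$len != kb$len) return(ka$len > kb$len)
      ka$id < kb$id
    }
    for (id in ids) {
      r <- 1L
      for (other in ids) if (other != id && better(other, id)) r <- r + 1L
      out[id] <- r
    }
  }
  out
}

small_sim_config <- function(...) {
  args <- list(
    n_genes = 40L, n_tissues = 54L, donors_per_tissue_range = c(4L, 10L),
    seed = 42L
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
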