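#' @importFrom stats pnorm rlnorm rpois runif
#' @importFrom utils head
NULL

# C-locale (radix) sorting so tissue/transcript orderings are identical on
# every platform regardless of LC_COLLATE.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

txrep_error <- function(class, msg) {
  stop(structure(
    class = c(class, "txrep_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Construct an expression matrix
#'
#' Bundles a dense transcript x sample TPM matrix with an optional
#' sample-to-tissue assignment and optional per-transcript description
#' (the GCT "Description" column). TPM values must be complete (no `NA`)
#' and non-negative; transcript and sample identifiers must be unique.
#'
#' @param tpm Numeric matrix of TPM values, transcripts in rows (rownames =
#'   transcript ids) and samples in columns (colnames = sample ids).
#' @param sample_tissue Optional named character vector mapping every sample
#'   id to a tissue label (attached later via [attach_sample_tissue()] when
#'   reading from files).
#' @param description Optional named character vector of per-transcript
#'   descriptions, preserved on write.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, sample_tissue = NULL, description = NULL) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    txrep_error("txrep_value_error", "tpm must be a numeric matrix")
  }
  if ((nrow(tpm) > 0L && is.null(rownames(tpm))) ||
      (ncol(tpm) > 0L && is.null(colnames(tpm)))) {
    txrep_error("txrep_value_error", "tpm must have transcript rownames and sample colnames")
  }
  if (nrow(tpm) == 0L && is.null(rownames(tpm))) rownames(tpm) <- character(0)
  if (ncol(tpm) == 0L && is.null(colnames(tpm))) colnames(tpm) <- character(0)
  if (anyDuplicated(rownames(tpm))) {
    txrep_error("txrep_value_error", "duplicated transcript ids in tpm rownames")
  }
  if (anyDuplicated(colnames(tpm))) {
    txrep_error("txrep_value_error", "duplicated sample ids in tpm colnames")
  }
  if (anyNA(tpm)) {
    txrep_error("txrep_value_error", "missing values are not permitted in a TPM matrix")
  }
  if (nrow(tpm) > 0L && ncol(tpm) > 0L && min(tpm) < 0) {
    txrep_error("txrep_value_error", "negative TPM values are not permitted")
  }
  if (!is.null(sample_tissue)) {
    sample_tissue <- validate_sample_tissue(sample_tissue, colnames(tpm))
  }
  if (!is.null(description)) {
    description <- as.character(description)
    if (length(description) != nrow(tpm)) {
      txrep_error("txrep_value_error", "description length must equal the number of transcripts")
    }
    names(description) <- rownames(tpm)
  }
  structure(
    list(tpm = tpm, sample_tissue = sample_tissue, description = description),
    class = "expression_matrix"
  )
}

validate_sample_tissue <- function(sample_tissue, sample_ids) {
  sample_tissue <- vapply(sample_tissue, as.character, character(1))
  if (is.null(names(sample_tissue)) || anyDuplicated(names(sample_tissue))) {
    txrep_error("txrep_value_error", "sample_tissue must be uniquely named by sample id")
  }
  missing <- setdiff(sample_ids, names(sample_tissue))
  if (length(missing)) {
    txrep_error(
      "txrep_value_error",
      sprintf(
        "%d sample(s) lack a tissue label (e.g. %s)",
        length(missing), paste(head(missing, 3L), collapse = ", ")
      )
    )
  }
  st <- sample_tissue[sample_ids]
  if (any(is.na(st)) || any(!nzchar(st))) {
    txrep_error("txrep_value_error", "empty tissue labels are not permitted")
  }
  st
}

#' @export
dim.expression_matrix <- function(x) dim(x$tpm)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d transcripts x %d samples%s\n",
    nrow(x$tpm), ncol(x$tpm),
    if (is.null(x$sample_tissue)) " (no tissue assignment)"
    else sprintf(", %d tissues", length(unique(x$sample_tissue)))
  ))
  invisible(x)
}

#' Transcript ids of an expression or tissue matrix
#' @param x An `expression_matrix` or `tissue_matrix`.
#' @return Character vector of transcript ids in matrix order.
#' @export
transcript_ids <- function(x) {
  if (inherits(x, "expression_matrix")) rownames(x$tpm)
  else if (inherits(x, "tissue_matrix")) rownames(x$values)
  else txrep_error("txrep_value_error", "unsupported object")
}

#' Construct a transcript annotation table
#'
#' Validates a per-transcript annotation data frame: unique transcript ids,
#' ORF length not exceeding transcript length, and consistent gene name /
#' gene biotype within each gene.
#'
#' @param df Data frame with columns `transcript_id`, `gene_id`, `gene_name`,
#'   `gene_biotype`, `transcript_biotype`, `transcript_length` (nt, > 0) and
#'   `orf_length` (nt, >= 0; 0 for non-coding transcripts).
#'
#' @return The validated data frame, classed `annotation_table`.
#' @export
annotation_table <- function(df) {
  required <- c(
    "transcript_id", "gene_id", "gene_name", "gene_biotype",
    "transcript_biotype", "transcript_length", "orf_length"
  )
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    txrep_error(
      "txrep_schema_error",
      paste("annotation is missing column(s):", paste(missing, collapse = ", "))
    )
  }
  df <- df[required]
  for (col in required[1:5]) df[[col]] <- as.character(df[[col]])
  df$transcript_length <- as.integer(df$transcript_length)
  df$orf_length <- as.integer(df$orf_length)
  if (anyDuplicated(df$transcript_id)) {
    txrep_error("txrep_annotation_error", "duplicated transcript_id in annotation")
  }
  if (nrow(df)) {
    if (any(is.na(df$transcript_length)) || any(df$transcript_length <= 0L)) {
      txrep_error("txrep_annotation_error", "transcript_length must be a positive integer")
    }
    if (any(is.na(df$orf_length)) || any(df$orf_length < 0L)) {
      txrep_error("txrep_annotation_error", "orf_length must be a non-negative integer")
    }
    if (any(df$orf_length > df$transcript_length)) {
      bad <- df$transcript_id[df$orf_length > df$transcript_length]
      txrep_error(
        "txrep_annotation_error",
        sprintf("orf_length exceeds transcript_length for %s", paste(head(bad, 3L), collapse = ", "))
      )
    }
    per_gene <- tapply(
      paste(df$gene_name, df$gene_biotype, sep = "\r"),
      df$gene_id,
      function(v) length(unique(v))
    )
    if (any(per_gene > 1L)) {
      txrep_error(
        "txrep_annotation_error",
        sprintf(
          "inconsistent gene_name/gene_biotype within gene(s): %s",
          paste(head(names(per_gene)[per_gene > 1L], 3L), collapse = ", ")
        )
      )
    }
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Construct a tissue-level mean expression matrix
#'
#' @param values Numeric matrix of per-tissue mean TPM, transcripts in rows,
#'   tissues in columns.
#' @param n_samples Named integer vector of per-tissue sample counts (all
#'   >= 1), names matching `colnames(values)`.
#'
#' @return An object of class `tissue_matrix`.
#' @export
tissue_matrix <- function(values, n_samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    txrep_error("txrep_value_error", "values must be a numeric matrix")
  }
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    txrep_error("txrep_value_error", "values must have transcript rownames and tissue colnames")
  }
  if (nrow(values) == 0L && is.null(rownames(values))) rownames(values) <- character(0)
  n_samples <- as.integer(n_samples[colnames(values)])
  names(n_samples) <- colnames(values)
  if (any(is.na(n_samples)) || any(n_samples < 1L)) {
    txrep_error("txrep_config_error", "every tissue needs a sample count >= 1")
  }
  if (nrow(values) > 0L && min(values) < 0) {
    txrep_error("txrep_value_error", "tissue mean TPM cannot be negative")
  }
  structure(
    list(values = values, n_samples = n_samples),
    class = "tissue_matrix"
  )
}

#' @export
dim.tissue_matrix <- function(x) dim(x$values)

#' @export
print.tissue_matrix <- function(x, ...) {
  cat(sprintf(
    "<tissue_matrix> %d transcripts x %d tissues (%d samples)\n",
    nrow(x$values), ncol(x$values), sum(x$n_samples)
  ))
  invisible(x)
}
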