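#' Read a GCT v1.2 expression matrix
#'
#' Parses the Gene Cluster Text format used by GTEx expression releases:
#' a `#1.2` version line, a `<n_rows>\t<n_cols>` dimensions line, then a
#' header row with an id column, an optional `Description` column, and one
#' column per sample. Declared and parsed dimensions must agree, every cell
#' must be numeric, and missing values are rejected unless `na_as_zero` is
#' set (the pipeline assumes complete TPM matrices).
#'
#' @param path Path to a GCT file.
#' @param na_as_zero Convert `NA` cells to 0 (with a reported count) instead
#'   of failing. Default `FALSE`.
#' @param strip_versions Drop trailing `.N` version suffixes from transcript
#'   ids (matching against annotation is exact-string otherwise).
#'   Default `FALSE`.
#'
#' @return An [expression_matrix()] without a tissue assignment (attach one
#'   with [attach_sample_tissue()]).
#' @seealso [write_gct()]
#' @export
read_gct <- function(path, na_as_zero = FALSE, strip_versions = FALSE) {
  if (!file.exists(path)) {
    txrep_error("txrep_io_error", sprintf("file not found: %s", path))
  }
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !grepl("^#1\\.2[ \t]*$", hdr[1L])) {
    txrep_error(
      "txrep_format_error",
      sprintf("not a GCT v1.2 file (first line %s)", deparse(if (length(hdr)) hdr[1L] else ""))
    )
  }
  dims <- suppressWarnings(as.integer(strsplit(hdr[2L], "\t", fixed = TRUE)[[1L]]))
  if (length(dims) != 2L || anyNA(dims) || any(dims < 0L)) {
    txrep_error("txrep_format_error", "malformed GCT dimensions line")
  }
  n_rows <- dims[1L]
  n_cols <- dims[2L]
  dt <- data.table::fread(
    path,
    skip = 2L, header = TRUE, sep = "\t",
    colClasses = list(character = 1L), data.table = TRUE, showProgress = FALSE
  )
  has_desc <- ncol(dt) == n_cols + 2L &&
    identical(tolower(names(dt)[2L]), "description")
  n_id_cols <- if (has_desc) 2L else 1L
  if (ncol(dt) - n_id_cols != n_cols || nrow(dt) != n_rows) {
    txrep_error(
      "txrep_dimension_error",
      sprintf(
        "GCT declares %d x %d but file contains %d row(s) and %d sample column(s)",
        n_rows, n_cols, nrow(dt), ncol(dt) - n_id_cols
      )
    )
  }
  ids <- dt[[1L]]
  if (strip_versions) ids <- sub("\\.[0-9]+$", "", ids)
  description <- if (has_desc) as.character(dt[[2L]]) else NULL
  sample_ids <- names(dt)[(n_id_cols + 1L):ncol(dt)]
  tpm <- matrix(
    NA_real_, nrow = n_rows, ncol = n_cols,
    dimnames = list(ids, sample_ids)
  )
  for (j in seq_len(n_cols)) {
    col <- dt[[n_id_cols + j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad)) {
        txrep_error(
          "txrep_value_error",
          sprintf(
            "non-numeric value %s in row '%s', column '%s'",
            deparse(col[bad[1L]]), ids[bad[1L]], sample_ids[j]
          )
        )
      }
      col <- num
    }
    tpm[, j] <- as.numeric(col)
  }
  if (anyNA(tpm)) {
    n_na <- sum(is.na(tpm))
    if (!na_as_zero) {
      txrep_error(
        "txrep_value_error",
        sprintf("%d missing cell(s) in GCT; use na_as_zero = TRUE to convert to 0", n_na)
      )
    }
    message(sprintf("read_gct: converted %d NA cell(s) to 0", n_na))
    tpm[is.na(tpm)] <- 0
  }
  expression_matrix(tpm, description = description)
}

#' Write an expression matrix as GCT v1.2
#'
#' Writes the canonical form read back by [read_gct()]: version line, tab
#' separated dimensions line, `Name`/`Description` header, then one row per
#' transcript. Values are written with up to 15 significant digits, so a
#' write/read round trip reproduces values to that precision. Transcripts
#' without a description get the GTEx placeholder `"na"`.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  desc <- x$description
  if (is.null(desc)) desc <- rep("na", nrow(x$tpm))
  dt <- data.table::data.table(
    Name = rownames(x$tpm),
    Description = unname(desc)
  )
  for (j in seq_len(ncol(x$tpm))) {
    data.table::set(dt, j = colnames(x$tpm)[j], value = x$tpm[, j])
  }
  writeLines(
    c("#1.2", sprintf("%d\t%d", nrow(x$tpm), ncol(x$tpm))),
    path
  )
  data.table::fwrite(
    dt, path,
    sep = "\t", quote = FALSE, append = TRUE, col.names = TRUE
  )
  invisible(path)
}

#' Read a sample-attribute table
#'
#' Reads a TSV in the GTEx SampleAttributesDS dialect and returns the
#' sample-to-tissue assignment. Extra columns are ignored; duplicate rows
#' for a sample are tolerated only when they agree on the tissue.
#'
#' @param path Path to the TSV.
#' @param id_column Name of the sample-id column (GTEx: `SAMPID`).
#' @param tissue_column Name of the tissue-subtype column (GTEx: `SMTSD`).
#'
#' @return Named character vector: `sample_id -> tissue label`.
#' @export
read_sample_attributes <- function(path, id_column = "SAMPID", tissue_column = "SMTSD") {
  dt <- data.table::fread(
    path,
    sep = "\t", header = TRUE, data.table = TRUE,
    showProgress = FALSE, colClasses = "character"
  )
  missing <- setdiff(c(id_column, tissue_column), names(dt))
  if (length(missing)) {
    txrep_error(
      "txrep_schema_error",
      paste("sample attributes missing column(s):", paste(missing, collapse = ", "))
    )
  }
  ids <- dt[[id_column]]
  tissues <- dt[[tissue_column]]
  if (any(is.na(tissues)) || any(!nzchar(tissues))) {
    txrep_error("txrep_value_error", "empty tissue label in sample attributes")
  }
  keep <- !duplicated(paste(ids, tissues, sep = "\r"))
  ids <- ids[keep]
  tissues <- tissues[keep]
  if (anyDuplicated(ids)) {
    bad <- unique(ids[duplicated(ids)])
    txrep_error(
      "txrep_conflict_error",
      sprintf(
        "sample id(s) assigned to more than one tissue: %s",
        paste(head(bad, 3L), collapse = ", ")
      )
    )
  }
  stats::setNames(tissues, ids)
}

#' Attach a sample-to-tissue assignment to an expression matrix
#'
#' Joins the attribute map onto the matrix columns. Samples present in the
#' expression matrix but absent from the attributes are dropped with a
#' warning (keeping them would silently misassign tissues); attribute rows
#' without a matching expression column are reported and ignored.
#'
#' @param x An [expression_matrix()].
#' @param sample_tissue Named character vector from [read_sample_attributes()].
#' @return The expression matrix restricted to labelled samples, with
#'   `sample_tissue` set.
#' @export
attach_sample_tissue <- function(x, sample_tissue) {
  stopifnot(inherits(x, "expression_matrix"))
  ids <- colnames(x$tpm)
  unmatched_expr <- setdiff(ids, names(sample_tissue))
  unmatched_attr <- setdiff(names(sample_tissue), ids)
  if (length(unmatched_attr)) {
    message(sprintf(
      "attach_sample_tissue: %d attribute row(s) have no expression column",
      length(unmatched_attr)
    ))
  }
  if (length(unmatched_expr)) {
    warning(sprintf(
      "attach_sample_tissue: dropping %d sample(s) without tissue attributes",
      length(unmatched_expr)
    ), call. = FALSE)
    keep <- setdiff(ids, unmatched_expr)
    if (!length(keep)) {
      txrep_error("txrep_config_error", "no samples remain after joining tissue attributes")
    }
    x$tpm <- x$tpm[, keep, drop = FALSE]
  }
  expression_matrix(
    x$tpm,
    sample_tissue = sample_tissue[colnames(x$tpm)],
    description = x$description
  )
}

#' Read / write transcript annotation as TSV
#'
#' The TSV carries the [annotation_table()] columns (`transcript_id`,
#' `gene_id`, `gene_name`, `gene_biotype`, `transcript_biotype`,
#' `transcript_length`, `orf_length`).
#'
#' @param path Path to the TSV.
#' @return [read_annotation_tsv()]: an [annotation_table()].
#' @export
read_annotation_tsv <- function(path) {
  dt <- data.table::fread(
    path,
    sep = "\t", header = TRUE, data.table = FALSE, showProgress = FALSE
  )
  annotation_table(dt)
}

#' @rdname read_annotation_tsv
#' @param x An [annotation_table()].
#' @export
write_annotation_tsv <- function(x, path) {
  stopifnot(inherits(x, "annotation_table"))
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Derive transcript annotation from a GENCODE-style GTF
#'
#' Reads a GTF (1-based, inclusive coordinates) and derives per-transcript
#' annotation: `transcript_length` is the summed length of the transcript's
#' `exon` features; `orf_length` is the summed length of its `CDS` features
#' plus `stop_codon` features when present (GENCODE CDS excludes the stop
#' codon), and 0 for non-coding transcripts. Attribute keys `gene_type` /
#' `transcript_type` (GENCODE) or `gene_biotype` / `transcript_biotype`
#' (Ensembl) are both accepted.
#'
#' @param path Path to a GTF file.
#' @return An [annotation_table()].
#' @export
read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    txrep_error("txrep_io_error", "read_annotation_gtf requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  pick <- function(a, b) if (a %in% names(df)) a else if (b %in% names(df)) b else NA_character_
  gb_col <- pick("gene_type", "gene_biotype")
  tb_col <- pick("transcript_type", "transcript_biotype")
  if (!all(c("gene_id", "transcript_id", "type") %in% names(df)) || is.na(gb_col)) {
    txrep_error("txrep_annotation_error", "GTF lacks gene_id/transcript_id/biotype attributes")
  }
  feat <- df[!is.na(df$transcript_id) & df$type %in% c("exon", "CDS", "stop_codon"), ]
  if (!nrow(feat)) {
    txrep_error("txrep_annotation_error", "GTF contains no exon/CDS features")
  }
  # lengths under the 1-based inclusive convention: end - start + 1 == width
  exon_len <- tapply(
    feat$width[feat$type == "exon"],
    feat$transcript_id[feat$type == "exon"], sum
  )
  cds <- feat$type %in% c("CDS", "stop_codon")
  cds_len <- tapply(feat$width[cds], feat$transcript_id[cds], sum)
  no_exon <- setdiff(names(cds_len), names(exon_len))
  if (length(no_exon)) {
    txrep_error(
      "txrep_annotation_error",
      sprintf("transcript(s) with CDS but no exon: %s", paste(head(no_exon, 3L), collapse = ", "))
    )
  }
  tx_ids <- sort_c(names(exon_len))
  meta <- feat[!duplicated(feat$transcript_id), , drop = FALSE]
  rownames(meta) <- meta$transcript_id
  n_gene <- tapply(feat$gene_id, feat$transcript_id, function(g) length(unique(g)))
  if (any(n_gene > 1L)) {
    txrep_error(
      "txrep_annotation_error",
      sprintf(
        "transcript id(s) assigned to multiple genes: %s",
        paste(head(names(n_gene)[n_gene > 1L], 3L), collapse = ", ")
      )
    )
  }
  gene_name <- if ("gene_name" %in% names(meta)) meta[tx_ids, "gene_name"] else meta[tx_ids, "gene_id"]
  gene_name <- ifelse(is.na(gene_name), meta[tx_ids, "gene_id"], gene_name)
  tb <- if (!is.na(tb_col)) meta[tx_ids, tb_col] else rep(NA_character_, length(tx_ids))
  tb <- ifelse(is.na(tb), meta[tx_ids, gb_col], tb)
  annotation_table(data.frame(
    transcript_id = tx_ids,
    gene_id = meta[tx_ids, "gene_id"],
    gene_name = gene_name,
    gene_biotype = meta[tx_ids, gb_col],
    transcript_biotype = tb,
    transcript_length = as.integer(exon_len[tx_ids]),
    orf_length = as.integer(ifelse(is.na(cds_len[tx_ids]), 0L, cds_len[tx_ids])),
    stringsAsFactors = FALSE
  ))
}

#' Write a tissue matrix (and its sample counts) as TSV
#'
#' @param x A [tissue_matrix()].
#' @param path Output TSV (transcripts as rows, tissues as columns).
#' @param n_samples_path Optional TSV path for the per-tissue sample counts.
#' @return `path`, invisibly.
#' @export
write_tissue_matrix <- function(x, path, n_samples_path = NULL) {
  stopifnot(inherits(x, "tissue_matrix"))
  dt <- data.table::data.table(transcript_id = rownames(x$values))
  for (j in seq_len(ncol(x$values))) {
    data.table::set(dt, j = colnames(x$values)[j], value = x$values[, j])
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  if (!is.null(n_samples_path)) {
    data.table::fwrite(
      data.table::data.table(tissue = names(x$n_samples), n_samples = as.integer(x$n_samples)),
      n_samples_path, sep = "\t", quote = FALSE
    )
  }
  invisible(path)
}
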