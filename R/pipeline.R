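#' Run the representative-tissue-transcript pipeline end to end
#'
#' Applies the full analysis to an expression matrix with tissue
#' assignment: restrict to transcripts of protein-coding genes, remove
#' transcripts with no expression in any sample, average to tissue level,
#' build per-transcript profiles (rank, Z-scores, CV, representative
#' tissues at the `tau` cutoff), and derive the summary tables. Filter-
#' stage transcript counts are logged in pipeline order (total ->
#' protein-coding genes -> expressed) so a real-data run can be audited
#' line by line.
#'
#' @param expression An [expression_matrix()] with `sample_tissue` attached.
#' @param annotation An [annotation_table()] covering the matrix.
#' @param tau Z cutoff, default 3.
#' @param sd_mode `"population"` (default) or `"sample"` SD.
#' @param thresholds TPM thresholds for the category table, default
#'   `c(1, 10, 100)`.
#' @param tpm_basis TPM basis for the category table thresholds, default
#'   `"overall_mean"`.
#' @param max_rank Largest rank in the rank-stratified table, default 10.
#' @param donor_weighted Donor-weighted overall means (see
#'   [overall_mean()]). Default `FALSE`.
#' @param outdir Optional directory; when given, all tables plus a JSON run
#'   manifest are written there.
#' @return List of class `txrep_run`: `profiles`, `tissue_matrix`,
#'   `gene_shares`, `category_table`, `tissue_report`, `rank_table`,
#'   `switch_events`, and `counts` (named filter-stage counts:
#'   `total`, `protein_coding`, `removed_unexpressed`, `analyzed`).
#' @export
run_pipeline <- function(expression, annotation, tau = 3,
                         sd_mode = c("population", "sample"),
                         thresholds = c(1, 10, 100),
                         tpm_basis = c("overall_mean", "representative_max"),
                         max_rank = 10L,
                         donor_weighted = FALSE,
                         outdir = NULL) {
  stopifnot(inherits(expression, "expression_matrix"), inherits(annotation, "annotation_table"))
  sd_mode <- match.arg(sd_mode)
  tpm_basis <- match.arg(tpm_basis)
  if (tau <= 0) txrep_error("txrep_config_error", "tau must be positive")

  n_total <- nrow(expression$tpm)
  pc <- filter_protein_coding(expression, annotation)
  n_pc <- nrow(pc$tpm)
  expressed <- drop_unexpressed(pc)
  n_removed <- attr(expressed, "n_removed")
  n_analyzed <- nrow(expressed$tpm)
  message(sprintf(
    "run_pipeline: %d transcripts -> %d of protein-coding genes -> %d expressed (removed %d)",
    n_total, n_pc, n_analyzed, n_removed
  ))

  tm <- tissue_means(expressed)
  shares <- gene_tpm_and_shares(tm, annotation)
  profiles <- transcript_profiles(
    tm, annotation,
    tau = tau, sd_mode = sd_mode, donor_weighted = donor_weighted
  )
  res <- structure(list(
    profiles = profiles,
    tissue_matrix = tm,
    gene_shares = shares,
    category_table = category_table(profiles, thresholds = thresholds, tpm_basis = tpm_basis),
    tissue_report = tissue_report(profiles),
    rank_table = rank_table(profiles, max_rank = max_rank),
    switch_events = switch_events(profiles),
    counts = c(
      total = n_total, protein_coding = n_pc,
      removed_unexpressed = n_removed, analyzed = n_analyzed
    )
  ), class = "txrep_run")

  if (!is.null(outdir)) {
    write_run(res, outdir, parameters = list(
      tau = tau, sd_mode = sd_mode, thresholds = thresholds,
      tpm_basis = tpm_basis, max_rank = max_rank,
      donor_weighted = donor_weighted,
      tail_probability = tail_probability(tau)
    ))
  }
  res
}

#' Write a pipeline run's tables and manifest
#'
#' Writes the profile TSV, all summary tables, the tissue-mean matrix with
#' its sample counts, and `manifest.json` recording parameters, the
#' filter-stage counts in pipeline order, and package/R versions. Outputs
#' are byte-deterministic for identical inputs and parameters.
#'
#' @param res A `txrep_run` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param parameters Named list recorded in the manifest.
#' @return Named character vector of file paths, invisibly.
#' @export
write_run <- function(res, outdir, parameters = list()) {
  stopifnot(inherits(res, "txrep_run"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    profiles = file.path(outdir, "profiles.tsv"),
    category_table = file.path(outdir, "category_table.tsv"),
    tissue_report = file.path(outdir, "tissue_report.tsv"),
    rank_table = file.path(outdir, "rank_table.tsv"),
    switch_events = file.path(outdir, "switch_events.tsv"),
    tissue_means = file.path(outdir, "tissue_means.tsv"),
    n_samples = file.path(outdir, "tissue_n_samples.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)
  write_profiles(res$profiles, paths[["profiles"]])
  data.table::fwrite(as.data.frame(res$category_table), paths[["category_table"]], sep = "\t", quote = FALSE)
  data.table::fwrite(res$tissue_report, paths[["tissue_report"]], sep = "\t", quote = FALSE)
  data.table::fwrite(res$rank_table, paths[["rank_table"]], sep = "\t", quote = FALSE)
  data.table::fwrite(res$switch_events, paths[["switch_events"]], sep = "\t", quote = FALSE)
  write_tissue_matrix(res$tissue_matrix, paths[["tissue_means"]], paths[["n_samples"]])
  manifest <- list(
    parameters = parameters,
    counts = as.list(res$counts),
    n_tissues = ncol(res$tissue_matrix$values),
    versions = list(
      txrep = as.character(utils::packageVersion("txrep")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- TRUE
  invisible(paths)
}

#' @export
print.txrep_run <- function(x, ...) {
  cat(sprintf(
    "<txrep_run> %d transcripts analyzed (%d input, %d protein-coding, %d unexpressed removed), %d tissues\n",
    x$counts[["analyzed"]], x$counts[["total"]],
    x$counts[["protein_coding"]], x$counts[["removed_unexpressed"]],
    ncol(x$tissue_matrix$values)
  ))
  cat(sprintf(
    "categories: %s\n",
    paste(sprintf(
      "%s:%d", x$category_table$category, x$category_table$n_transcripts
    ), collapse = " ")
  ))
  invisible(x)
}

#' Run the pipeline from files
#'
#' File-based front end: reads the GCT expression matrix, sample
#' attributes and annotation (TSV, or GTF when the path ends in `.gtf`),
#' joins them and calls [run_pipeline()]. Input MD5 checksums are added to
#' the manifest when `outdir` is given.
#'
#' @param gct Path to the GCT v1.2 expression file.
#' @param sample_attributes Path to the sample-attribute TSV.
#' @param annotation Path to the annotation TSV or GTF.
#' @param id_column,tissue_column Sample-attribute column names (GTEx:
#'   `SAMPID`, `SMTSD`).
#' @param strip_versions Strip `.N` version suffixes from GCT transcript
#'   ids before matching annotation.
#' @param na_as_zero Convert NA cells in the GCT to 0.
#' @param ... Passed to [run_pipeline()].
#' @inheritParams run_pipeline
#' @return A `txrep_run`.
#' @export
run_pipeline_files <- function(gct, sample_attributes, annotation,
                               id_column = "SAMPID", tissue_column = "SMTSD",
                               strip_versions = FALSE, na_as_zero = FALSE,
                               outdir = NULL, ...) {
  em <- read_gct(gct, na_as_zero = na_as_zero, strip_versions = strip_versions)
  st <- read_sample_attributes(sample_attributes, id_column = id_column, tissue_column = tissue_column)
  em <- attach_sample_tissue(em, st)
  ann <- if (grepl("\\.gtf(\\.gz)?$", annotation)) {
    read_annotation_gtf(annotation)
  } else {
    read_annotation_tsv(annotation)
  }
  res <- run_pipeline(em, ann, outdir = outdir, ...)
  if (!is.null(outdir)) {
    manifest_path <- file.path(outdir, "manifest.json")
    manifest <- jsonlite::read_json(manifest_path)
    manifest$inputs <- list(
      gct = unname(tools::md5sum(gct)),
      sample_attributes = unname(tools::md5sum(sample_attributes)),
      annotation = unname(tools::md5sum(annotation))
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
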