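#!/usr/bin/env Rscript

# Recipe for reproducing the full GTEx v8 analysis. NOT run by the test
# suite: it needs two multi-gigabyte downloads from the GTEx Portal
# (https://gtexportal.org/home/datasets) and a GENCODE 26 GTF:
#
#   GTEx_Analysis_2017-06-05_v8_RSEMv1.3.0_transcript_tpm.gct.gz
#   GTEx_Analysis_v8_Annotations_SampleAttributesDS.txt
#   gencode.v26.annotation.gtf.gz
#
# Decompress the GCT, place the three files in the working directory (or
# pass paths below), then run this script. The filter-stage counts logged
# by the pipeline (total records -> transcripts of protein-coding genes ->
# expressed) can be audited line by line, and manifest.json records the
# cutoff, SD convention and tail probability used.

suppressPackageStartupMessages(library(txrep))

args <- commandArgs(trailingOnly = TRUE)
gct <- if (length(args) >= 1) args[1] else "GTEx_Analysis_2017-06-05_v8_RSEMv1.3.0_transcript_tpm.gct"
attrs <- if (length(args) >= 2) args[2] else "GTEx_Analysis_v8_Annotations_SampleAttributesDS.txt"
gtf <- if (length(args) >= 3) args[3] else "gencode.v26.annotation.gtf.gz"
outdir <- if (length(args) >= 4) args[4] else "gtex_v8_run"

res <- run_pipeline_files(
  gct = gct,
  sample_attributes = attrs,
  annotation = gtf,
  strip_versions = FALSE,   # GTEx transcript ids carry versions matching GENCODE 26
  tau = 3,
  sd_mode = "population",   # rerun with "sample" to gauge the SD ambiguity
  outdir = outdir
)
print(res)
print(res$category_table)
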