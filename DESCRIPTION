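Package: txrep
Title: Representative Tissue Transcripts from Transcript-Level TPM Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies representative tissue transcripts of protein-coding
    genes from a transcript-by-sample TPM matrix. Provides readers and writers
    for GCT v1.2 expression matrices, GTEx-style sample-attribute tables and
    transcript annotation (TSV or GENCODE-style GTF); biotype and expression
    filtering; per-tissue aggregation; within-gene transcript ranking with
    ORF-length and transcript-length tie-breaks; cross-tissue Z-score
    classification of tissue-restricted expression (Z >= 3) with coefficient
    of variation; summary tables (tissue-count categories, per-tissue reports,
    rank-stratified summaries, isoform-switch flags, top-gene exports); and a
    seeded synthetic-data generator with planted ground truth for end-to-end
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
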