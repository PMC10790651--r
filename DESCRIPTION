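Package: bacsc
Title: Per-Cell Bacterial Transcript Quantification for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies bacterial 16S-derived transcripts per host single
    cell by joining cell-barcode/UMI-tagged alignments with read-level
    taxonomic classifications, merging gene-expression and 16S-enrichment
    library quantifications with UMI deduplication, and analysing the host
    transcriptome conditional on per-cell bacterial status (thresholded
    cell classification, Wilcoxon differential expression, preranked
    gene-set enrichment). Includes a synthetic-data generator with known
    ground truth for end-to-end validation, and a file-driven stage runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
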