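Package: pmeth
Title: Comparative Placental Methylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative whole-genome bisulfite sequencing (WGBS)
    analysis of placental methylomes: per-CpG methylation call ingestion,
    fixed-window methylation tracks and density summaries, segmentation of
    partially methylated domains (PMDs) and highly methylated domains (HMDs)
    with a two-state Gaussian hidden Markov model, cross-species coordinate
    lifting through UCSC chain files with synteny-level cleaning and
    differential-region calling, gene-body and feature methylation summaries
    with promoter/CpG-island masking, genic-location prediction from
    methylation (spinograms), a binned co-independence test of gene-body
    methylation against expression, and a fully deterministic synthetic
    methylome generator used to validate every step end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
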