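Package: digiscaff
Title: Digital Scaffolding of Draft Genome Assemblies and Nanopore Run
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reference-guided ordering of draft-assembly contigs from BLAST
    tabular alignments.  Builds gene- and ranked-query probe sets from a
    reference genome, computes per query-contig coverage with successive
    threshold filtering, orders contigs into a positive-cell incidence grid,
    selects a minimal complete scaffold (a smallest ordered contig selection
    giving linear chromosome coverage), estimates the linear coverage
    percentage, and flags repeat-rich regions.  Also splits long nanopore
    reads into fixed-length non-overlapping k-mers with a homopolymer census,
    and computes flow-cell run-comparison statistics (one-sample and paired
    t-tests, two-way repeated-measures ANOVA, throughput summaries).  A
    synthetic-data generator provides genomes with planted repeats,
    fragmented contig sets, gene annotations and long reads with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    IRanges,
    methods,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
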