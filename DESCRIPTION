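Package: dmrlink
Title: Differential DNA Methylation Calling and Methylome-Transcriptome
    Association for Two-Condition Bisulfite Sequencing Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of two-condition whole-genome
    bisulfite sequencing (WGBS) paired with RNA-seq. Starting from
    per-cytosine methylation count tables, the package estimates bisulfite
    conversion rates from unmethylated spike-in controls, calls
    methylcytosines with a conversion-adjusted binomial test, detects
    differentially methylated cytosines (Fisher's exact test) and regions
    (a seed-and-extend scan over CG/CHG/CHH motifs with exact Wilcoxon
    rank-sum testing), associates methylation changes with genes and
    transposable elements (metagene bins, distance profiles, hypergeometric
    enrichment), calls differentially expressed genes and transposons, and
    links differentially methylated regions to expression changes to
    nominate putative epiregulated genes. A fully deterministic synthetic
    data generator emulates the two-condition WGBS + RNA-seq design with
    planted differentially methylated regions and expression effects so
    that every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
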