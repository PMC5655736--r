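Package: methexpress
Title: Tissue-Comparative DNA Methylome and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing whole-genome bisulfite-sequencing
    methylomes and RNA-seq transcriptomes across tissues. Implements binomial
    methylated-cytosine calling against a spike-in non-conversion rate with
    Benjamini-Hochberg FDR control, weighted methylation levels, metagene
    methylation profiles (20-bp flank windows and 100 exon-concatenated
    gene-body bins), sliding-window Fisher-exact detection of differentially
    methylated regions with the 30/70 classification rule, per-gene
    hypermethylation tests, methylation-state PCA, CPM/RPKM expression
    normalisation with expressed-gene filtering and quartile stratification,
    a negative-binomial exact test for differential expression,
    pairwise-slope coexpression, and hypergeometric GO and transcription-factor
    family enrichment. A synthetic-data generator with known ground truth
    (planted DMRs, DE genes, coexpression modules, spike-in controls) makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
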