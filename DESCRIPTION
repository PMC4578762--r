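Package: crossnet
Title: Cross-Genus Conserved Regulatory Network Inference from
    Developmental Expression and Conserved Non-Coding Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers gene-regulatory associations conserved between two
    nematode genera from developmental RNA-seq and genome sequence.
    Classifies 1:1 orthologs by conservation of stage-specific expression
    (binarized thresholds and cosine similarity), calls conserved sequence
    blocks by windowed nucleotide identity and partitions them into coding
    and non-coding, discovers motifs in conserved non-coding regions with a
    ZOOPS expectation-maximization finder, scans position weight matrices
    with exact dynamic-programming p-values and Benjamini-Hochberg
    q-values, filters redundant and unmappable motifs, associates motif
    hits with nearest genes, computes GO-term enrichment of
    motif-associated gene sets in both lineages, intersects enriched
    associations across genera into bipartite motif-gene networks, and
    checks the result against a randomized-GO negative control. A seeded
    synthetic-world generator emulates all required inputs with planted
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
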