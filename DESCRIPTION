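Package: clipSiteR
Title: Transition-Centered Identification of RNA-Protein Interaction Sites in PAR-CLIP Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls RNA-binding-protein interaction sites from PAR-CLIP sequencing data.
    A Bayesian-network mixture model over relative substitution frequencies scores
    crosslink-induced base transitions (T->C for 4SU, G->A for 6SG) with posterior
    log-odds, the Mini-Rank Norm algorithm resolves cluster boundaries at high
    resolution from strand-specific coverage fluctuations, and matched RNA-Seq data
    yields experimentally based false discovery rate bounds for sites and clusters.
    Includes miRNA seed-enrichment analysis against dinucleotide-shuffled backgrounds
    and a seeded synthetic-data generator producing aligned reads with known truth.
License: GPL-2
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
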