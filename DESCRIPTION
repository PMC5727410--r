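Package: rhscan
Title: Detection and Comparative Analysis of T6SS-Associated Rhs Toxin
    Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying type VI secretion system (T6SS) effector
    repertoires in bacterial genomes, centred on the Rhs family of
    polymorphic toxins. Detects Rhs genes from genome assemblies by
    open-reading-frame scanning and degenerate YD-repeat/PAAR motif
    matching, splits each gene into its conserved core and C-terminal
    toxin domain at the DPXG(18)DPXG motif, pairs toxins with their
    downstream immunity genes and flags orphaned immunity genes and
    pseudogenes, clusters toxin domains at a nucleotide-identity
    threshold and builds strain-by-toxin co-occurrence networks, screens
    genomes for T6SS and toxin presence with identity-times-coverage
    scores, and provides the supporting statistics (TPM normalisation,
    rank correlation, one-way ANOVA with Tukey HSD, Nei-Gojobori dN/dS,
    neighbour-joining trees and Robinson-Foulds congruence). A
    synthetic-genome generator with full ground truth makes every stage
    testable without external data.
License: MIT
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
    ape,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
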