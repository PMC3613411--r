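Package: GeneLossKit
Title: Pseudogene Detection, Synteny-Based Deletion Calling, and
    Phylogenetic Mapping of Gene-Loss Events
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the loss of a protein-coding gene across
    vertebrate genomes. Detects coding-sequence-disrupting mutations
    (frameshifts, premature stop codons, splice-dinucleotide changes) in
    candidate loci by affine-gap exon alignment against a reference gene
    model, classifies per-species gene status, distinguishes true gene
    deletion from assembly gaps using conserved flanking-gene synteny,
    maps the minimum number of irreversible inactivation events on a
    species tree by Dollo parsimony, and tests whether intact open
    reading frames are cryptic pseudogenes with Tajima relative-rate
    tests and neighbor-joining protein trees with bootstrap support. A
    tree-based simulator generates multi-exon gene families with injected
    inactivating mutations and a matching truth table, so the whole
    pipeline is testable without any external data. Bundled fixtures
    transcribe a published census of glucokinase regulatory protein
    (GCKR) gene structures across vertebrates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn,
    phytools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, ComparativeGenomics, Alignment
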