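Package: gcdrift
Title: Clade-Specific GC Enrichment in Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and characterisation of clade-specific GC enrichment
    in protein-coding genes. Implements a non-stationary nucleotide
    substitution model with per-clade equilibrium GC content (T92-style),
    maximum-likelihood parameter fitting and marginal ancestral sequence
    reconstruction on a fixed rooted phylogeny, directional A/T to G/C
    substitution accounting along branches, conservative versus radical
    amino-acid replacement rates under a GC-based amino-acid grouping,
    codon-usage enrichment and amino-acid carbon-economy comparisons
    between clades, and FPKM-threshold classification of life-phase
    specific gene expression. A built-in simulator evolves in-frame codon
    alignments along a known tree with clade-specific equilibrium GC and
    records true ancestral sequences and substitution events, so every
    analysis stage can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
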