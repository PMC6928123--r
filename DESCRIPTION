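Package: cubphylo
Title: Codon Usage Bias Profiling and Housekeeping-Gene Phylogenetics for
    Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Per-gene and per-genome codon usage bias profiling of bacterial
    coding sequences: Wright's effective number of codons (Nc), GC content at
    third codon positions (GC3/GC3s), Kyte-Doolittle hydropathy (GRAVY), and
    Nc-plot diagnosis of selection versus mutational pressure against the
    mutation-only expectation curve. Aggregates whole-genome summaries,
    contrasts housekeeping genes (rpoB, atpD, infB, trpB) against their host
    genomes with rank-based tests, and quantifies phylogenetic congruence
    between housekeeping-gene trees and a 16S rRNA reference using Kimura
    two-parameter distances, neighbor-joining, bootstrap consensus and
    Robinson-Foulds distances. Includes a seeded synthetic-genome and
    sequence-evolution simulator so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
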