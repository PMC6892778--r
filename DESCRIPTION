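Package: pathMG
Title: Mutated Pathway and Sub-Pathway Discovery from Somatic Mutation
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies pathways mutated in significantly more tumour samples
    than expected under a per-sample mutation-count-preserving random null,
    extracts connected sub-pathways whose member-gene mutations jointly cover
    a large fraction of a cohort (common sub-pathways) or maximise the
    mutation-coverage difference between two cancer subtypes
    (subtype-specific sub-pathways) by greedy search on pathway interaction
    graphs, and reports cancer-gene and drug-target enrichment of the
    resulting gene sets. Includes readers for MAF variant tables, binary
    mutation matrices, GMT gene sets and per-pathway edge lists, a synthetic
    cohort generator with planted signals for benchmarking, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
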