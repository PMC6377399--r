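Package: ltrdyn
Title: Birth-Death Dynamics of LTR Retrotransposons from Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural detection of long terminal repeat retrotransposons
    (LTR-RTs) in genome assemblies, classification of element remnants into
    solo-LTRs and truncated elements from flanking Gag-Pol protein homology,
    insertion-age dating from LTR-LTR divergence under the Kimura
    two-parameter model, Silix-style single-linkage family clustering, and
    removal-rate (S:I, T:I) and gene-proximity statistics. Includes a
    synthetic-genome simulator that plants intact, solo and truncated
    elements with known ages, target site duplications and family labels so
    the whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
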