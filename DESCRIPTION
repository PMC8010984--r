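Package: sinescout
Title: Discovery and Characterization of SINE Retrotransposon Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, self-contained pipeline for short interspersed nuclear
    element (SINE) discovery and characterization in genome assemblies:
    thresholded seed-and-extend homology search, majority-rule consensus
    reconstruction from genomic copies, structural annotation (RNA polymerase
    III promoter boxes, simple-repeat 3' tails, target site duplications,
    empty-site boundary refinement), Kimura two-parameter divergence and
    relative-age profiling, insertion-context classification against gene
    models, partner-LINE discovery via shared 3' tails, and horizontal
    transposon transfer candidate screening with orthologous empty-site
    corroboration. Includes a synthetic-genome simulator with full ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
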