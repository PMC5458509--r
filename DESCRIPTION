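Package: ppiseq
Title: Pooled Double-Barcode Sequencing Analysis of Protein-Protein
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of pooled protein-fragment complementation screens
    read out by double-barcode lineage tracking. Parses double-barcode
    sequencing reads, corrects counts for PCR chimeras, infers per-lineage
    relative fitness by global Poisson maximum likelihood with a
    self-consistent population mean-fitness correction, aggregates lineage
    fitnesses into protein-protein interaction scores with
    Bonferroni-corrected tests against reporter-free controls, detects
    environment-dependent (dynamic) interactions, and provides a generative
    simulator of the pooled serial-dilution experiment for validation,
    together with library-scalability calculators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
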