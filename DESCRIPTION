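Package: pepscanr
Title: Linear B-Cell Epitope Mapping from Overlapping Peptide ELISA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pepscan-style linear B-cell epitope mapping of
    autoantibody responses, built around the anti-ADAMTS13 serology workup
    used in immune-mediated thrombotic thrombocytopenic purpura. Designs
    overlapping peptide libraries (fixed-length windows at a constant
    offset), parses ELISA plate measurements with blank subtraction,
    duplicate averaging and negative-control cut-offs, deconvolves
    per-patient positive peptides into merged epitope regions with
    maximal-coverage cores, classifies domain reactivity, summarises
    shared and non-shared epitopes across a cohort, quantifies total
    immunoglobulin from four-parameter-logistic standard curves, and
    implements the mixing-study Bethesda titration for inhibitor
    quantification. A seeded synthetic-cohort generator with planted
    epitopes and inhibitor titres supports end-to-end parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    minpack.lm,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
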