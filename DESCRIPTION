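Package: repwell
Title: Repertoire Diversity from Replicate-Well Immunosequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative B-cell receptor repertoire analysis from
    multi-well replicate immunosequencing designs. Implements single-mismatch
    consensus collapse of sequencing errors, presence/absence ("occupancy")
    digital clone counting across replicate PCR wells, maximum-likelihood
    estimation of repertoire richness and clonality under a gamma-mixed
    Poisson abundance model, germline V(D)J assignment with CDR3 extraction
    and somatic hypermutation calling, and descriptive repertoire statistics
    (sample overlap, V usage, CDR3 length distributions, per-position
    hypermutation profiles with AID hotspot/coldspot motif annotation).
    Includes a synthetic-data generator that emulates the 188-well urn
    design so every pipeline stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
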