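Package: barcodeconcord
Title: Concordance of COI Barcode Species Delimitations with Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for DNA-barcode (COI) datasets: trims
    alignments to a guaranteed common overlap, computes uncorrected
    p-distance matrices with pairwise deletion, delimits putative species
    with a recursive barcode-gap method, single-linkage clustering (a BIN
    proxy with a best-match fallback) and a single-threshold general mixed
    Yule-coalescent model, compares study sequences against a local
    reference library, and classifies discordances between morphological
    identifications and molecular putative species (splitting/lumping
    categories, method-resolution flag, study-only vs merged-data context),
    including resolution of provisionally named morphospecies. A seeded
    synthetic-data generator produces aligned barcode sets with a known
    species truth and injected discordance scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
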