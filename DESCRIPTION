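Package: zpmod
Title: Phylogenetic and Structural Analysis of Zona Pellucida Module Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for molecular-evolutionary analysis of zona pellucida (ZP)
    module families under alignment uncertainty. Implements branch support from
    replicate alignments (branch recovery proportions and transfer bootstrap
    expectations on a majority-rule consensus), minimal ancestor deviation (MAD)
    and midpoint rooting, normalized and branch-length-weighted Robinson-Foulds
    distances, cysteine-anchored domain demarcation and per-domain gap-profile
    scanning for clade-level domain loss, and geometry-based disulfide
    plausibility calls with Type 1/2/3 cysteine-connectivity classification
    mapped on the tree by Fitch parsimony. Includes a synthetic-data generator
    that plants domain-loss clades, connectivity types and disulfide pairs with
    known truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phytools,
    Biostrings,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
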