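Package: seedscan
Title: Accessibility-Based RNA-RNA Interaction Prediction with Seed and
    Interaction Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constrained minimum-free-energy prediction of RNA-RNA
    interactions for bacterial sRNA target screens. Interactions are scored
    as the sum of a nearest-neighbor hybridization energy and two
    accessibility penalties ED = -RT*ln(Pu) derived from exact region-wise
    unpaired probabilities of a McCaskill-style intramolecular ensemble.
    Provides the full suite of seed constraints (seed length, GU
    prohibition, seed energy and accessibility thresholds) and interaction
    constraints (length, energy, accessibility, loop size), pluggable
    energy-parameter files, brute-force verification oracles, a start-codon
    window extraction and top-N recovery benchmarking pipeline, and a
    deterministic synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
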