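Package: phylomut
Title: Phylogenomic Somatic Mutation Detection and Rate Estimation in
    Individual Plants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects somatic mutations from replicated whole-genome
    sequencing of branch tips arranged on the known physical architecture
    of an individual plant. Implements a phylogenetic diploid genotype
    likelihood model with a per-metre mutation kernel and pruning over the
    physical tree, replicate-aware read likelihoods, de novo mutation
    probability (DNP) and model-fit (LLD) scores, the positive-control and
    de novo filter cascades, exhaustive-topology parsimony and
    path-difference null tests, in silico read-spiking false-negative
    estimation, replicate-label permutation false-discovery estimation,
    conversion of corrected mutation counts to per-metre, per-year and
    per-generation rates, and a synthetic data generator emulating the
    replicated branch-tip study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vcfR,
    Biostrings,
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
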