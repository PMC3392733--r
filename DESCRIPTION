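Package: qpcrstab
Title: Reference Gene Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting stable reference (housekeeping) genes from
    RT-qPCR quantification-cycle (Cq) data. Implements efficiency-corrected
    delta-Cq transformation to relative quantities, the geNorm pairwise-variation
    stability measure with stepwise elimination and normalization-factor
    pairwise variation, the NormFinder model-based inter/intra-group variance
    decomposition, the BestKeeper descriptive/correlation index, an independent
    nonparametric validation (Kruskal-Wallis with Bonferroni correction,
    Kendall rank correlation against sampling time) with a consensus ranking,
    REST-style relative expression of target genes with a randomization test,
    and a seeded simulator of Cq datasets with presets that emulate
    multi-group, multi-timepoint fish rearing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
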