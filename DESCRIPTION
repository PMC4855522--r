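Package: wmemcover
Title: Weighted Mutually Exclusive Maximum Set Cover for Cancer Driver Discovery
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact branch-and-bound solver for the weighted mutually exclusive
    maximum set cover problem, with the tumor-cohort preprocessing that turns
    somatic-genome-alteration matrices and gene signatures into solver
    instances.  Given a universe of tumors and weighted candidate gene sets,
    the solver returns the pairwise-disjoint subfamily that covers the most
    tumors with minimum total weight, using component decomposition and
    degree-driven branching with an effective branching factor below 1.325.
    Includes hypergeometric gene weighting, signature-based tumor
    stratification into perturbed and normal-like subsets, module enrichment
    scoring, and seeded synthetic-data generators for solver instances and
    full cohorts.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
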