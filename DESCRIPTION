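Package: fluxkit
Title: Constraint-Based Modelling of Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Flux-balance analysis and related constraint-based methods for
    metabolic network models: a sparse stoichiometric model representation
    with gene-protein-reaction boolean rules, a BiGG-style tab-separated
    reaction-list reader and writer, a build-once/modify-in-place
    optimisation-problem layer with a reference LP/QP/MILP backend, the
    algorithms FBA, minimal total flux, MOMA, linear MOMA and ROOM, and
    high-level batch analyses (k-wise gene deletion, reaction deletion, flux
    variability, robustness and phenotypic phase plane scans) that reuse one
    problem handle across thousands of re-solves.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
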