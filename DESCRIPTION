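Package: metammi
Title: AMMI Analysis and Yield-Stability Selection for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Additive Main effects and Multiplicative Interaction (AMMI)
    analysis of balanced multi-environment variety trials. Provides S4
    containers for replicate-level RCBD trial records and genotype-by-
    environment cell-mean matrices, the stratified two-way analysis of
    variance, the singular value decomposition of the double-centered
    interaction matrix with symmetric square-root score scaling and
    approximate F-tests with Gollob degrees of freedom, the AMMI stability
    value (ASV) and genotype selection index (GSI), AMMI1/AMMI2 biplot
    coordinates, per-environment genotype selections, a seeded synthetic
    trial generator with planted low-rank interaction for validation, and
    an end-to-end reporting pipeline. Ships a published 69-hybrid by
    5-location maize grain-yield reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'anova.R'
    'ammi.R'
    'stability.R'
    'biplot.R'
    'trial-io.R'
    'fixture.R'
    'metammi-package.R'
    'synthetic.R'
    'pipeline.R'
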