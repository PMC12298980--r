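Package: emfkit
Title: Ecosystem Multifunctionality Indices, Microbial Taxa Screens and
    Driver Attribution for Disturbance Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how land-use disturbance (for example
    utility-scale solar facility installation and operation) changes
    ecosystem multifunctionality (EMF) and which microbial, plant and
    environmental factors drive the change. Computes averaging and
    multithreshold multifunctionality indices from plot-level function
    tables, annualised effect sizes with bootstrap confidence intervals,
    taxonomic, phylogenetic (Faith's PD) and functional (Gower-distance
    FDis) alpha diversity, indicator-species analysis (IndVal) with
    permutation tests, co-occurrence network keystone classification by
    within-module degree (Zi) and participation coefficient (Pi),
    microbial activity indices (metabolic quotient, Cmic/Corg), a driver
    attribution battery (variance partitioning, LMG relative importance,
    partial correlation, Mantel tests, random-forest importance) and
    piecewise structural equation models evaluated by d-separation and
    Fisher's C. Includes a synthetic-study generator with planted ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    igraph,
    ranger,
    jsonlite,
    yaml,
    withr
Suggests:
    cluster,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
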