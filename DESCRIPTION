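Package: fibrilmech
Title: Coarse-Grained Tensile Mechanics of Cross-Linked Collagen Fibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained bead-chain models of D-periodically
    staggered collagen type I fibrils, inserts breakable advanced-glycation
    endproduct (AGE) cross-links of configurable stiffness, strength and
    density, and performs destructive constant-velocity tensile tests with a
    compiled velocity-Verlet engine. Provides the trilinear breakable bond
    law, the per-bond loading energy capacity and the cross-link/backbone
    energy-balance criterion for fibrillar stiffening, plus analysis of
    stress-strain curves (elastic limit, peak stress, elastic-to-peak stress
    difference), inter-molecular sliding versus molecular stretching energy
    partition, broken-bond censuses, and parameter-sweep orchestration with
    tidy outputs and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
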