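Package: foundress
Title: Multilevel Selection and Cooperative Colony Founding in Harvester Ants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of the evolution of cooperative
    (pleometrotic) colony founding in harvester ant queens under multilevel
    selection. Foundresses cluster on a toroidal landscape, fight within
    nascent colonies, and compete between colonies with a queen-number
    productivity advantage; parameter sweeps locate the interaction-radius
    threshold at which the tolerant phenotype fixes. Companion tools
    implement Pearson chi-square tests on contingency tables (no continuity
    correction), aggression summaries, Kaplan-Meier and log-rank utilities
    for foundress survival records, quadrat-count Monte Carlo tests of
    complete spatial randomness, and seed-deterministic generators for
    synthetic foundress experiments and spatial point patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
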