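Package: mutnetsim
Title: Agent-Based Simulation and Analysis of Mutualistic Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates plant-animal mutualistic communities as populations of
    host and visitor agents that negotiate resource exchanges through a staged
    interaction protocol (habitat matching, trait matching, trait-size
    complementarity, resource negotiation). Successful exchanges are
    aggregated into weighted bipartite interaction networks, and a metrics
    suite computes the structural descriptors used to characterise mutualistic
    webs: connectance, NODF nestedness with the isocline of perfect
    nestedness, interaction-frequency and degree distributions with power-law
    fits, and species dependence distributions. Includes seeded replicate
    experiments, parameter sweeps for sensitivity analysis, and command-line
    entry points with CSV, GraphML and JSON exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
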