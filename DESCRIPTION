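Package: synchimera
Title: Stimulation-Evoked Synchronization Patterns and Chimera States on
    Aging Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates delay-coupled stochastic Wilson-Cowan neural mass
    dynamics on weighted structural connectomes, stimulates single brain
    regions after tuning the global coupling to the critical regime, and
    classifies the evoked cognitive-system synchronization pattern as
    synchronous, asynchronous, or chimera via Kuramoto order parameters
    and modularity-based community detection. Includes a seeded generator
    of synthetic connectome cohorts with modular block structure, a
    rich-club core and configurable age trajectories, structural graph
    measures (strength, participation coefficient, weighted rich club,
    distance to the rich club), and age-stratified statistics over the
    resulting synchronization patterns (class proportions, pattern
    prevalence tiers, pattern similarity and its region/individual
    decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
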