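Package: moodtune
Title: Multi-Objective Optimization Design for Tuning Synthetic Gene Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based tuning of synthetic gene circuits by multi-objective
    optimization design (MOOD), instantiated on the incoherent type-1
    feed-forward loop (I1-FFL) adaptation circuit. Simulates a reduced
    deterministic kinetic model of the circuit (stiff ODEs with a compiled
    right-hand side), scores candidate parameterizations by inverse
    sensitivity and inverse precision under a protein-B excursion constraint,
    approximates the Pareto front with a differential-evolution optimizer
    using an external archive, spherical pruning and an objective-space
    pertinency box, extracts wet-lab tuning guidelines by hierarchical
    clustering of the Pareto set with Kruskal-Wallis screening, computes
    cluster-annotated Level-Diagram tables, and analyzes single-knob sweeps
    and downstream-load (retroactivity) robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
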