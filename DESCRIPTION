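Package: rnmsim
Title: Semi-Quantitative Dynamics of Signed Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Build, validate and simulate signed protein-interaction
    regulatory networks with a fuzzy-logic interpolation of Boolean rules:
    each node carries a continuous activation level in [0,1] driven by a
    sigmoid activation of its aggregate regulator input and first-order
    decay. Provides random-initial-condition baseline ensembles with
    attractor clustering, sustained-activation (clamping) perturbation and
    rescue protocols with node-wise Mann-Whitney comparison, two-level
    full-factorial ANOVA sensitivity screening with Pareto reporting, a
    constrained random-network generator for synthetic fixtures, and
    import/export of edge-list CSV/TSV, SIF and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
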