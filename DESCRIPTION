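Package: rhizomorph
Title: Morphometrics and Stochastic Growth Simulation of Chytrid Rhizoid Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the development of chytrid fungal rhizoids from
    traced reconstructions in the SWC neuron-morphology format. Computes a
    morphometric suite for rooted geometric trees (total length, tip and
    bifurcation counts, rhizoidal growth unit, bifurcation angles, surface area,
    maximum Euclidean distance, convex-hull cover area), detects and classifies
    apical versus lateral branch events in time series, estimates box-counting
    fractal dimension globally and in sliding windows, fits per-cell growth rates
    and compartment elongation rates, and performs group comparisons with
    significance annotation. Includes a seeded stochastic rhizoid growth simulator
    with carbon-replete, carbon-starved and particle-contact presets that emits
    SWC time series with ground-truth branch event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
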