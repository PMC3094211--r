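Package: refate
Title: Boolean Network Simulation and In-Silico Cell-Fate Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Synchronous Boolean network modeling of gene-regulatory networks
    with signed edges, logical AND nodes and per-node tie-breaking modes
    (self-degradation, self-sustaining, self-activation). Provides attractor
    and basin-of-attraction estimation by convergent random sampling with an
    exhaustive-enumeration oracle for small networks, de-novo phenotype
    prediction (sporulation efficiency, cell-cycle phase assignment and
    viability calls, Matthews correlation evaluation), exhaustive search and
    scoring of cell-fate reprogramming recipes (potency, efficiency,
    heterogeneity deviation, Pareto filtering), sampled potential-landscape
    estimation via a noisy state-transition matrix with a pseudo-state, and
    state-transition flux analysis to locate transition states shared across
    reprogramming recipes. Includes degree-preserving network randomization
    for null-model significance testing, a programmatic random-network
    generator, and packaged fixtures: an 11-node budding-yeast cell-cycle
    network and a synthetic reconstruction of a 56-node cell-cycle plus
    sporulation network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
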