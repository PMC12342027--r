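Package: consortnet
Title: Graph-Based Stochastic Simulation of Signal Propagation in
    Engineered Bacterial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time, graph-based stochastic simulator of molecular
    signal propagation in engineered bacterial consortia.  Nodes are cells
    carrying substrate, hydrogen peroxide, autoinducer-1 (AI-1) and GFP
    weights; undirected edges are communication channels along which
    inducers diffuse by a discrete graph-Laplacian scheme.  Supports
    chemically induced (bulk hydrogen peroxide addition) and
    electrogenetically induced (electrode source node) Monoculture and
    Transmitter/Receiver systems, substrate-gated stochastic cell division
    with edge inheritance, per-step edge randomization emulating stirred
    cultures versus static biofilms, and partially fixed subpopulations.
    Includes endpoint and time-series metrics (median GFP, percent active
    nodes, species means, Louvain modularity, fold change between edge
    modes), scenario presets, seeded replicate batches, and GraphML/CSV
    serialization of network snapshots.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
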