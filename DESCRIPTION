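Package: firstmover
Title: First-Mover Analysis of Developmental Connectome Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the order in which neurons are born and wire
    into a developing connectome, modelled on Caenorhabditis elegans
    embryogenesis. Given a table of neuron birth times and a table of directed
    chemical synapses classified by developmental stability (transient,
    developmental, stable), the package computes signed birth-time differences,
    assigns each cell one or more of five leader-follower wiring strategies
    (N-P coupling, XOR First Mover, XOR Second Mover, XNOR, P-N coupling), and
    summarises the population: strategy frequencies, pairwise overlaps,
    stability-class composition, birth-time cumulative distributions, and
    synaptic density by birth time. A Stackelberg-style sequential growth
    simulator and a synthetic-data generator with planted strategies make every
    stage testable without external data; in-text reference tables (strategy
    cell lists, probabilistic strategy profile, stage family counts, strategy
    frequencies) are bundled as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
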