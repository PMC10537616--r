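Package: sirw
Title: Self-Interacting Random Walks with a Lennard-Jones Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of self-interacting random walks in
    continuous three-dimensional space. Each step of the growing walk is
    drawn by Boltzmann-weighted sampling over a near-uniform candidate
    direction set on the sphere, with weights given by the walker's
    Lennard-Jones interaction with all previously visited positions. The
    package computes trajectory order parameters (radius of gyration and a
    turning-window helix fraction), ensemble averages over independent
    seeded runs, temperature and well-depth sweeps with transition
    temperature estimation and the linear transition-line fit between the
    transition temperature and the potential well depth, and reads and
    writes trajectories as XYZ files or PDB alpha-carbon traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
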