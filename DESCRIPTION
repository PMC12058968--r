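Package: cohesim
Title: Cohesive, Aligning Active Brownian Particles: Simulation and State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates two-dimensional overdamped active Brownian particles that
    interact through purely repulsive Weeks-Chandler-Andersen forces, reciprocal
    alignment torques and non-reciprocal cohesive torques sharing one interaction
    range. Provides initial-condition families (lattice, hexagonal cluster, aster,
    worm), static and dynamic observables (polar order, periodic-boundary cluster
    analysis, cluster size and system size, mean squared displacement and
    orientation correlation with analytic active-Brownian baselines, gyration-tensor
    asymmetry, neighbor turnover), a rule-based classifier for the six emergent
    collective states (disperse, multiple worm, line, persistent worm, rotary worm,
    aster) with parameter-sweep state diagrams, and numerical torque-balance
    stability analyses for idealized sheet geometries that explain edge-particle
    tilt and tip-particle stability in worm formations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
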