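Package: smalpr
Title: Coarse-Grained Styrene-Maleic Acid Copolymer Models and Membrane
    Nanodisk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds parametric coarse-grained topologies for styrene-maleic
    acid (SMA) copolymers in the Martini bead convention, maps atomistic
    trajectories onto pseudo-coarse-grained beads, derives bonded parameters
    by direct Boltzmann inversion with iterative distribution matching
    against a Metropolis Monte Carlo bonded-ensemble sampler, and quantifies
    membrane-disruption observables on coarse-grained trajectories: radius
    of gyration, density profiles and ion asymmetry, grid-based pore
    detection and kinetics, lipid flip-flop, aggregate detection, and
    SMA-lipid-particle (SMALP) nanodisk characterization. Ships a synthetic
    fixture generator for planted bilayers, pores, nanodisks, and
    Boltzmann-distributed bonded ensembles, plus GRO/PDB/ITP-dialect
    readers and writers and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    graphics,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
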