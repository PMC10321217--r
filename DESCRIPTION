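Package: nanostargel
Title: Coarse-Grained Simulation of DNA Nanostar Hydrogels with Tunable
    Planarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid-body Brownian dynamics of trivalent DNA nanostars modelled
    as patchy particles with a tunable planarity parameter d_p, together with
    the analysis pipeline for the gels they self-assemble into: contact
    graphs and melting curves, network connectivity metrics, radial
    distribution functions, bending-angle statistics, mean squared
    displacements, Green-Kubo zero-shear viscosity via a multiple-tau stress
    correlator, and a generic well-tempered metadynamics engine with a
    planarity collective variable. All quantities are in reduced units
    (bead diameter sigma, energy epsilon, Brownian time tau_Br).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    igraph,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
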