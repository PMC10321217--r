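#' nanostargel: coarse-grained DNA nanostar hydrogels
#'
#' Rigid-body Brownian dynamics of trivalent DNA nanostars modelled as
#' patchy particles with tunable planarity, plus the full analysis pipeline
#' for the percolating gels they form: melting curves, contact-network
#' metrics, radial distribution functions, bending-angle statistics, mean
#' squared displacements and Green-Kubo zero-shear viscosity, and a generic
#' well-tempered metadynamics engine with a planarity collective variable.
#'
#' @useDynLib nanostargel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"
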