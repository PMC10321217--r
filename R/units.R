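#' Convert reduced quantities to laboratory units
#'
#' The simulation works entirely in reduced units: bead diameter
#' `sigma = 2.5 nm` (about 8 bp of dsDNA), thermal energy `k_B T`, and the
#' Brownian time `tau_Br = 3 pi eta_s sigma^3 / k_B T`, the time a bead
#' needs to diffuse its own size in a solvent of viscosity `eta_s`. These
#' helpers apply the mapping for documentation and reporting only; nothing
#' internal ever leaves reduced units.
#'
#' @param sigma_nm bead diameter in nanometres.
#' @param temperature_K absolute temperature.
#' @param eta_s_Pa_s solvent viscosity (water at room temperature by
#'   default).
#' @return `brownian_time_s()`: tau_Br in seconds. `eta_to_Pa_s()`: the
#'   viscosity in Pa s corresponding to a reduced viscosity in
#'   k_B T tau_Br / sigma^3.
#' @export
brownian_time_s <- function(sigma_nm = 2.5, temperature_K = 300,
                            eta_s_Pa_s = 1e-3) {
  kT <- 1.380649e-23 * temperature_K
  sigma <- sigma_nm * 1e-9
  3 * pi * eta_s_Pa_s * sigma^3 / kT
}

#' @param eta_reduced viscosity in k_B T tau_Br / sigma^3.
#' @rdname brownian_time_s
#' @export
eta_to_Pa_s <- function(eta_reduced, sigma_nm = 2.5, temperature_K = 300,
                        eta_s_Pa_s = 1e-3) {
  kT <- 1.380649e-23 * temperature_K
  sigma <- sigma_nm * 1e-9
  tau <- brownian_time_s(sigma_nm, temperature_K, eta_s_Pa_s)
  eta_reduced * kT * tau / sigma^3
}
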