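#' Force-field parameters for the patchy nanostar model
#'
#' Two pair interactions act between beads of different nanostars: a purely
#' repulsive truncated-shifted Lennard-Jones (WCA) between the finite-size
#' CORE/ARM beads (diameter sigma), and a short-range Morse attraction
#' between the patch sites that stand in for the self-complementary sticky
#' ends. The Morse well has depth `eps_m`, inverse width `a_m`, minimum at
#' `r0_m`, and is cut off at `r0_m + 0.2 sigma` so patches attract within a
#' 0.2 sigma radius of the bond minimum; the narrow range keeps the bond
#' single-valent. Patch sites carry no excluded volume, and patch-bead cross
#' interactions are ignored (patches sit on bead surfaces, so adding them
#' would double-count the contact repulsion).
#'
#' The default well depth and minimum position are calibrated so that the
#' melting point of the reference planar gel (volume fraction 0.01) sits at
#' T = 1.1 eps/k_B: the two-star association constant obtained by Monte
#' Carlo integration of this Hamiltonian, inserted into the Wertheim mass
#' -action relation `x/(1-x)^2 = rho_patch Delta(T)`, crosses x = 0.5 there.
#' The calibration is part of the model definition and is never adjusted at
#' run time; see the package vignette for the derivation.
#'
#' @param eps_rep excluded-volume strength (epsilon).
#' @param eps_m Morse well depth (epsilon); the calibrated gel-forming
#'   depth (the energy-shifted well is about 16 epsilon deep).
#' @param a_m Morse inverse width (1/sigma).
#' @param r0_m Morse minimum (sigma); near-contact, so bonded arms meet
#'   tip-to-tip and the bonded core-core distance `5 sigma + r0_m` sits at
#'   the 5-sigma first peak of the gel's radial distribution function.
#' @param shift shift the Morse energy to zero at the cutoff.
#' @param sigma bead diameter, the length unit.
#' @return an object of class `ns_ff`.
#' @export
ff_params <- function(eps_rep = 1, eps_m = 22, a_m = 10, r0_m = 0.05,
                      shift = TRUE, sigma = 1) {
  stopifnot(eps_rep > 0, eps_m >= 0, a_m > 0, r0_m >= 0)
  structure(
    list(eps_rep = eps_rep, eps_m = eps_m, a_m = a_m, r0_m = r0_m,
         r_cut_patch = r0_m + 0.2 * sigma, shift = shift, sigma = sigma),
    class = "ns_ff")
}

#' @export
print.ns_ff <- function(x, ...) {
  cat("Patchy nanostar force field (reduced units)\n")
  cat(sprintf("  WCA: eps_rep = %g, cutoff = 2^(1/6) sigma\n", x$eps_rep))
  cat(sprintf("  Morse: eps_m = %g, a_m = %g/sigma, r0 = %g, cutoff = %g%s\n",
              x$eps_m, x$a_m, x$r0_m, x$r_cut_patch,
              if (x$shift) " (shifted)" else ""))
  invisible(x)
}

#' WCA excluded-volume pair energy
#'
#' `4 eps_rep [(sigma/r)^12 - (sigma/r)^6] + eps_rep` for
#' `r < 2^(1/6) sigma`, zero beyond: purely repulsive.
#'
#' @param r pair distance(s), sigma; must be positive.
#' @param ff an [ff_params()] object.
#' @export
wca_energy <- function(r, ff = ff_params()) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  s6 <- (ff$sigma / r)^6
  ifelse(r < 2^(1 / 6) * ff$sigma, 4 * ff$eps_rep * (s6^2 - s6) + ff$eps_rep, 0)
}

#' Morse patch-patch pair energy
#'
#' `eps_m [(1 - exp(-a_m (r - r0_m)))^2 - 1]` for `r < r0_m + 0.2 sigma`
#' (optionally shifted to zero at the cutoff), zero beyond.
#'
#' @inheritParams wca_energy
#' @export
morse_energy <- function(r, ff = ff_params()) {
  stopifnot(all(r >= 0))
  sh <- if (ff$shift) {
    ff$eps_m * ((1 - exp(-ff$a_m * (ff$r_cut_patch - ff$r0_m)))^2 - 1)
  } else 0
  u <- ff$eps_m * ((1 - exp(-ff$a_m * (r - ff$r0_m)))^2 - 1) - sh
  ifelse(r < ff$r_cut_patch, u, 0)
}

ff_to_cpp <- function(ff) {
  list(eps_rep = ff$eps_rep, eps_m = ff$eps_m, a_m = ff$a_m, r0_m = ff$r0_m,
       r_cut_patch = ff$r_cut_patch, shift = isTRUE(ff$shift))
}

#' Forces, energy and virial of a configuration
#'
#' Evaluates the total pair energy, the per-bead forces `-grad U`, the virial
#' tensor `W_ab = sum_pairs r_a F_b` (minimum image) and the stress tensor
#' `P = W / V` for a simulation state or a raw bead frame. CORE/ARM beads of
#' different stars interact via WCA, patch pairs via Morse; intra-star pairs
#' are excluded (rigid body).
#'
#' @param x an `ns_state` (see [sim_state()]) or a list with elements
#'   `positions` (n x 3), `mol` (integer molecule ids), `type`
#'   (CORE/ARM/PATCH character or 0/1/2 integer codes) and `box_L`.
#' @param ff an [ff_params()] object.
#' @return list with `forces` (n x 3), `energy`, `virial` (3 x 3),
#'   `stress` (3 x 3, virial / volume) and `n_overlap` (bead pairs closer
#'   than 0.5 sigma, an integration-instability indicator; warns if > 0).
#' @export
compute_forces <- function(x, ff = ff_params()) {
  fr <- as_bead_frame(x)
  res <- cpp_bead_forces(fr$positions, fr$mol, fr$type_code, fr$box_L,
                         ff_to_cpp(ff))
  if (res$n_overlap > 0) {
    warning(sprintf("%d bead pair(s) closer than 0.5 sigma", res$n_overlap))
  }
  res$stress <- res$virial / fr$box_L^3
  res
}

# Normalise state-like input to a bead frame for the compiled routines.
as_bead_frame <- function(x) {
  if (inherits(x, "ns_state")) {
    tpl <- x$template
    pos <- cpp_world_beads(x$centers, x$quats, tpl$bead_positions)
    n <- nrow(x$centers)
    list(positions = pos,
         mol = rep(seq_len(n), each = 10L),
         type_code = rep(template_type_codes(tpl), n),
         arm = rep(tpl$arm_of_bead, n),
         box_L = x$box_L)
  } else {
    stopifnot(is.list(x), !is.null(x$positions), !is.null(x$mol),
              !is.null(x$type), !is.null(x$box_L))
    tc <- if (is.numeric(x$type)) as.integer(x$type)
          else match(x$type, c("CORE", "ARM", "PATCH")) - 1L
    arm <- x$arm
    if (is.null(arm)) {
      # recover arm ids from within-molecule bead order (template layout)
      idx <- stats::ave(seq_along(x$mol), x$mol, FUN = seq_along)
      arm <- c(NA, 1L, 1L, 2L, 2L, 3L, 3L, 1L, 2L, 3L)[idx]
    }
    list(positions = as.matrix(x$positions), mol = as.integer(x$mol),
         type_code = tc, arm = as.integer(arm), box_L = x$box_L)
  }
}
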