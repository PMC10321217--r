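#' Two-star association constant by Monte Carlo integration
#'
#' Independent equilibrium reference for the bonding thermodynamics of the
#' patchy model: the association constant of one specific patch pair,
#' `Delta(T) = integral over relative poses of (exp(-U/k_B T) - 1)`,
#' evaluated by importance sampling. One star is held fixed; the partner's
#' pose is sampled with its first patch displaced uniformly inside a sphere
#' around the fixed star's first patch (radius `r_cut + 0.2 sigma`, beyond
#' which the integrand vanishes up to the soft WCA background) and its
#' orientation uniform on SO(3). The full pair energy (all patch pairs plus
#' excluded volume) enters the Boltzmann factor, so steric gating by the
#' arms is included.
#'
#' This brute-force integral is used as an oracle against the dynamics: via
#' the Wertheim mass-action relation `x / (1 - x)^2 = rho_patch Delta(T)`
#' it predicts the equilibrium bonded fraction that long Brownian-dynamics
#' runs of the same Hamiltonian must reproduce, and it is the basis of the
#' force-field calibration (see [ff_params()]).
#'
#' @param d_p template planarity.
#' @param ff force field.
#' @param temperature temperature (eps / k_B).
#' @param n_samples Monte Carlo sample count.
#' @param seed RNG seed.
#' @return list with `Delta` (sigma^3), its standard error `se`, and the
#'   sample count.
#' @export
pair_association_constant <- function(d_p = 0, ff = ff_params(),
                                      temperature = 1,
                                      n_samples = 100000L, seed = 1) {
  rng <- local_rng(seed)
  on.exit(rng$restore())
  tpl <- ns_template(d_p)
  L <- 60
  ctr <- c(L, L, L) / 2
  beadsA <- sweep(tpl$bead_positions, 2, ctr, "+")
  typec <- template_type_codes(tpl)
  patchA <- beadsA[8, ]
  rs <- ff$r_cut_patch + 0.2
  vol <- 4 / 3 * pi * rs^3
  ffc <- ff_to_cpp(ff)
  qs <- random_quats(n_samples)
  d <- matrix(stats::runif(3 * n_samples * 2, -rs, rs), ncol = 3)
  d <- d[rowSums(d^2) < rs^2, , drop = FALSE]
  while (nrow(d) < n_samples) {
    extra <- matrix(stats::runif(3 * n_samples, -rs, rs), ncol = 3)
    d <- rbind(d, extra[rowSums(extra^2) < rs^2, , drop = FALSE])
  }
  d <- d[seq_len(n_samples), , drop = FALSE]
  mol <- rep(1:2, each = 10L)
  types <- c(typec, typec)
  beta <- 1 / temperature
  vals <- vapply(seq_len(n_samples), function(k) {
    R <- quat_to_matrix(qs[k, ])
    lb <- tpl$bead_positions %*% t(R)
    ctrB <- patchA + d[k, ] - lb[8, ]
    e <- cpp_bead_forces(rbind(beadsA, sweep(lb, 2, ctrB, "+")),
                         mol, types, L, ffc)$energy
    expm1(-beta * e)
  }, numeric(1))
  list(Delta = vol * mean(vals),
       se = vol * stats::sd(vals) / sqrt(n_samples),
       n = n_samples)
}

#' Equilibrium bonded fraction from the association constant
#'
#' Wertheim first-order mass action for a single self-complementary patch
#' type: with patch density `rho_p = 3 N / V` and pair constant `Delta`,
#' the bonded fraction solves `x / (1 - x)^2 = rho_p Delta`.
#'
#' @param Delta association constant (sigma^3); negative values (net
#'   repulsion) give 0.
#' @param rho_patch patch number density (1 / sigma^3).
#' @export
equilibrium_theta <- function(Delta, rho_patch) {
  k <- rho_patch * Delta
  ifelse(k <= 0, 0, (1 + 2 * k - sqrt(1 + 4 * k)) / (2 * k))
}
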