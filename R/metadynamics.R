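#' History-dependent Gaussian bias on a collective variable
#'
#' Container for a metadynamics bias `U_G(zeta) = sum_k w_k exp(-(zeta -
#' zeta_k)^2 / (2 delta^2))`. In well-tempered mode the height of each new
#' Gaussian is scaled by `exp(-U_G(zeta) / k_B dT)` at deposition, so the
#' accumulated bias converges instead of growing indefinitely.
#'
#' @param w Gaussian height (epsilon).
#' @param delta Gaussian width, in CV units.
#' @param stride deposition stride (steps), carried for the drivers.
#' @param well_tempered bias temperature `dT` (eps / k_B) or `NULL` for
#'   standard metadynamics.
#' @param temperature system temperature, used by the well-tempered
#'   free-energy rescaling.
#' @param bounds CV interval; deposits outside are clamped to the boundary
#'   with a warning.
#' @return an object of class `bias_potential`.
#' @export
bias_potential <- function(w = 0.1, delta = 0.05, stride = 500L,
                           well_tempered = NULL, temperature = 1,
                           bounds = c(-Inf, Inf)) {
  stopifnot(w > 0, delta > 0, length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(centers = numeric(0), heights = numeric(0),
                 w = w, delta = delta, stride = as.integer(stride),
                 well_tempered = well_tempered, temperature = temperature,
                 bounds = bounds),
            class = "bias_potential")
}

#' @export
print.bias_potential <- function(x, ...) {
  cat(sprintf(
    "Metadynamics bias: %d Gaussians (w = %g, delta = %g%s)\n",
    length(x$centers), x$w, x$delta,
    if (is.null(x$well_tempered)) ""
    else sprintf(", well-tempered dT = %g", x$well_tempered)))
  invisible(x)
}

#' Evaluate the accumulated bias
#'
#' @param bias a [bias_potential()].
#' @param zeta CV value(s).
#' @return `U_G(zeta)`, always non-negative.
#' @export
bias_energy <- function(bias, zeta) {
  if (length(bias$centers) == 0) return(rep(0, length(zeta)))
  d2 <- outer(zeta, bias$centers, "-")^2
  as.numeric(exp(-d2 / (2 * bias$delta^2)) %*% bias$heights)
}

bias_dudz <- function(bias, zeta) {
  if (length(bias$centers) == 0) return(rep(0, length(zeta)))
  d <- outer(zeta, bias$centers, "-")
  as.numeric((exp(-d^2 / (2 * bias$delta^2)) * (-d / bias$delta^2)) %*%
             bias$heights)
}

#' Deposit one Gaussian
#'
#' Appends a Gaussian at the current CV value. Well-tempered mode damps the
#' height by `exp(-U_G(zeta) / dT)` evaluated before the deposit, which
#' makes repeated deposits at one point decay geometrically. Out-of-bounds
#' CV values are clamped to the nearer boundary with a warning.
#'
#' @param bias a [bias_potential()].
#' @param zeta current CV value.
#' @return the updated bias.
#' @export
meta_deposit <- function(bias, zeta) {
  stopifnot(inherits(bias, "bias_potential"), length(zeta) == 1)
  if (zeta < bias$bounds[1] || zeta > bias$bounds[2]) {
    warning(sprintf("CV value %.4g outside bounds [%g, %g]; clamped",
                    zeta, bias$bounds[1], bias$bounds[2]))
    zeta <- min(max(zeta, bias$bounds[1]), bias$bounds[2])
  }
  h <- bias$w
  if (!is.null(bias$well_tempered)) {
    h <- h * exp(-bias_energy(bias, zeta) / bias$well_tempered)
  }
  bias$centers <- c(bias$centers, zeta)
  bias$heights <- c(bias$heights, h)
  bias
}

#' Bias force on the underlying coordinates
#'
#' Chain rule for biased dynamics: `F = -(dU_G/dzeta) * grad(zeta)`.
#'
#' @param bias a [bias_potential()].
#' @param zeta current CV value.
#' @param cv_gradient gradient of the CV with respect to the coordinates
#'   (any shape; returned force has the same shape).
#' @export
bias_force <- function(bias, zeta, cv_gradient) {
  -bias_dudz(bias, zeta) * cv_gradient
}

#' Free-energy-landscape estimate from the bias
#'
#' After long deposition the accumulated bias estimates the negative free
#' energy: `F(zeta) = -U_G(zeta)` up to a constant; in well-tempered mode
#' the estimate is rescaled by `(T + dT) / dT`. The profile is shifted so
#' its minimum is zero.
#'
#' @param bias a [bias_potential()].
#' @param grid CV values to evaluate on.
#' @return data frame with `zeta` and `F` (epsilon).
#' @export
estimate_fel <- function(bias, grid) {
  u <- bias_energy(bias, grid)
  f <- -u
  if (!is.null(bias$well_tempered)) {
    f <- f * (bias$temperature + bias$well_tempered) / bias$well_tempered
  }
  data.frame(zeta = grid, F = f - min(f))
}

#' Metadynamics on a 1D Brownian particle
#'
#' Overdamped dynamics `dx = -U'(x) dt / T * D + sqrt(2 D dt) xi` with the
#' history-dependent bias force added, depositing a Gaussian every `stride`
#' steps. The bias (and its derivative) is cached on a fine grid and
#' interpolated, so the cost per step does not grow with the number of
#' deposits.
#'
#' @param dU derivative of the target potential, a function of x.
#' @param bias a [bias_potential()] with finite bounds.
#' @param x0 starting position.
#' @param n_steps steps to run.
#' @param dt time step.
#' @param temperature temperature (D = 1).
#' @param seed RNG seed.
#' @param grid_n cache resolution.
#' @return list with the final `bias`, the visited `x` series (thinned), and
#'   the `fel` estimate on the cache grid.
#' @export
run_metadynamics_1d <- function(dU, bias, x0, n_steps, dt = 1e-3,
                                temperature = 1, seed = 1, grid_n = 512L) {
  stopifnot(all(is.finite(bias$bounds)))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  lo <- bias$bounds[1]; hi <- bias$bounds[2]
  grid <- seq(lo, hi, length.out = grid_n)
  dz <- grid[2] - grid[1]
  ug <- numeric(grid_n)       # cached U_G on grid
  dug <- numeric(grid_n)      # cached dU_G/dz on grid
  x <- x0
  thin <- max(1L, n_steps %/% 10000L)
  xs <- numeric(n_steps %/% thin)
  sqn <- sqrt(2 * dt)
  noise <- stats::rnorm(n_steps)
  for (s in seq_len(n_steps)) {
    if (s %% bias$stride == 0L) {
      zc <- min(max(x, lo), hi)
      h <- bias$w
      if (!is.null(bias$well_tempered)) {
        k <- 1 + (zc - lo) / dz
        k0 <- floor(k); fr <- k - k0
        u_here <- ug[k0] * (1 - fr) + ug[min(k0 + 1, grid_n)] * fr
        h <- h * exp(-u_here / bias$well_tempered)
      }
      bias$centers <- c(bias$centers, zc)
      bias$heights <- c(bias$heights, h)
      gg <- exp(-(grid - zc)^2 / (2 * bias$delta^2))
      ug <- ug + h * gg
      dug <- dug + h * gg * (-(grid - zc) / bias$delta^2)
    }
    k <- 1 + (min(max(x, lo), hi) - lo) / dz
    k0 <- floor(k); fr <- k - k0
    dug_x <- dug[k0] * (1 - fr) + dug[min(k0 + 1, grid_n)] * fr
    force <- -dU(x) - dug_x
    x <- x + force * dt / temperature + sqn * noise[s]
    # reflecting walls keep the particle in the CV window
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
    if (s %% thin == 0L) xs[s %/% thin] <- x
  }
  list(bias = bias, x = xs, fel = estimate_fel(bias, grid))
}

#' Double-well free-energy recovery demo
#'
#' Runs [run_metadynamics_1d()] on the quartic double well
#' `U(x) = b (x^2 - 1)^2` (barrier height `b` at x = 0, minima at x = +/-1)
#' and reports the recovered barrier.
#'
#' @param barrier barrier height b (epsilon).
#' @param n_steps,dt,temperature,seed see [run_metadynamics_1d()].
#' @param w,delta,stride,well_tempered bias settings.
#' @return list with `fel`, `barrier_est`, `barrier_true` and the run.
#' @export
double_well_demo <- function(barrier = 5, n_steps = 400000L, dt = 2e-3,
                             temperature = 1, seed = 1, w = 0.15,
                             delta = 0.12, stride = 250L,
                             well_tempered = 10) {
  bias <- bias_potential(w = w, delta = delta, stride = stride,
                         well_tempered = well_tempered,
                         temperature = temperature, bounds = c(-1.7, 1.7))
  dU <- function(x) 4 * barrier * x * (x^2 - 1)
  run <- run_metadynamics_1d(dU, bias, x0 = -1, n_steps = n_steps, dt = dt,
                             temperature = temperature, seed = seed)
  fel <- run$fel
  in_min1 <- abs(fel$zeta + 1) < 0.15
  in_min2 <- abs(fel$zeta - 1) < 0.15
  at_top <- abs(fel$zeta) < 0.1
  est <- mean(fel$F[at_top]) - min(mean(fel$F[in_min1]), mean(fel$F[in_min2]))
  list(fel = fel, barrier_est = est, barrier_true = barrier, run = run)
}

#' Planarity CV of a flexible Y-molecule, with gradient
#'
#' For a flexible four-bead Y (a core and three arm tips) the planarity
#' `d_p` is computed from the normalized core-to-tip vectors exactly as for
#' the rigid template, together with its analytic gradient with respect to
#' all four bead positions (chain rule through the normalization and the
#' plane fit). The gradient makes the CV usable for biased dynamics.
#'
#' @param core length-3 core position.
#' @param tips 3 x 3 matrix of arm-tip positions (rows).
#' @return list with `value` and `gradient` (4 x 3; rows core, tip1..3).
#' @export
dp_cv <- function(core, tips) {
  stopifnot(length(core) == 3, all(dim(tips) == c(3, 3)))
  v <- sweep(tips, 2, core, "-")
  r <- sqrt(rowSums(v^2))
  if (any(r < 1e-12)) stop("degenerate: tip coincides with core", call. = FALSE)
  e <- v / r
  e1 <- e[1, ]; e2 <- e[2, ]; e3 <- e[3, ]
  M <- cross3(e1, e2) + cross3(e2, e3) + cross3(e3, e1)
  nM <- sqrt(sum(M^2))
  if (nM < 1e-10) {
    stop("degenerate plane: normalized tips are colinear", call. = FALSE)
  }
  Mh <- M / nM
  D <- sum(e1 * cross3(e2, e3))
  s <- if (D >= 0) 1 else -1
  val <- s * D / nM
  # dD/de_i and d|M|/de_i = (e_j - e_k) x Mh by cyclic structure
  gD <- rbind(cross3(e2, e3), cross3(e3, e1), cross3(e1, e2))
  gM <- rbind(cross3(e2 - e3, Mh), cross3(e3 - e1, Mh), cross3(e1 - e2, Mh))
  ge <- s * (gD / nM - (D / nM^2) * gM)
  grad <- matrix(0, 4, 3)
  for (i in 1:3) {
    P <- (diag(3) - tcrossprod(e[i, ])) / r[i]
    gt <- as.numeric(P %*% ge[i, ])
    grad[1 + i, ] <- gt
    grad[1, ] <- grad[1, ] - gt
  }
  list(value = val, gradient = grad)
}

#' Metadynamics demo on a flexible Y-molecule
#'
#' A minimal flexible nanostar stand-in: four beads with harmonic core-tip
#' bonds (rest length 1) and harmonic tip-tip bonds (rest length sqrt(3),
#' the planar 120-degree geometry), whose unique energy minimum is the flat
#' Y (`d_p = 0`). Biasing the planarity CV pushes the molecule out of plane
#' and samples the full `d_p` range that plain dynamics at the same
#' temperature barely leaves.
#'
#' @param n_steps steps to run.
#' @param dt time step.
#' @param temperature temperature.
#' @param k_bond bond stiffness (both bond types).
#' @param bias a [bias_potential()]; `NULL` runs unbiased.
#' @param seed RNG seed.
#' @return list with the `d_p` time series (thinned), the final `bias` and
#'   the final coordinates.
#' @export
flexible_y_demo <- function(n_steps = 20000L, dt = 5e-4, temperature = 0.2,
                            k_bond = 100, bias = NULL, seed = 1) {
  rng <- local_rng(seed)
  on.exit(rng$restore())
  # start planar
  az <- c(0, 2, 4) * pi / 3
  pos <- rbind(c(0, 0, 0), cbind(cos(az), sin(az), 0))
  pairs_ct <- cbind(1, 2:4)                     # core-tip, rest 1
  pairs_tt <- rbind(c(2, 3), c(3, 4), c(2, 4))  # tip-tip, rest sqrt(3)
  rest <- c(rep(1, 3), rep(sqrt(3), 3))
  pairs <- rbind(pairs_ct, pairs_tt)
  sqn <- sqrt(2 * dt)
  thin <- max(1L, n_steps %/% 5000L)
  dps <- numeric(n_steps %/% thin)
  for (s in seq_len(n_steps)) {
    Fm <- matrix(0, 4, 3)
    for (b in seq_len(nrow(pairs))) {
      i <- pairs[b, 1]; j <- pairs[b, 2]
      d <- pos[i, ] - pos[j, ]
      rr <- sqrt(sum(d^2))
      f <- -k_bond * (rr - rest[b]) * d / rr
      Fm[i, ] <- Fm[i, ] + f
      Fm[j, ] <- Fm[j, ] - f
    }
    cv <- dp_cv(pos[1, ], pos[2:4, ])
    if (!is.null(bias)) {
      if (s %% bias$stride == 0L) bias <- meta_deposit(bias, cv$value)
      Fm <- Fm + bias_force(bias, cv$value, cv$gradient)
    }
    pos <- pos + Fm * dt / temperature +
      sqn * matrix(stats::rnorm(12), 4, 3)
    if (s %% thin == 0L) dps[s %/% thin] <- cv$value
  }
  list(d_p = dps, bias = bias, positions = pos)
}
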