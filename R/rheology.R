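#' Off-diagonal virial stress of a configuration
#'
#' `P_ab = (1/V) sum_pairs r_ab,a F_ab,b` over all interacting bead pairs
#' with minimum-image separations. The dynamics is overdamped, so the stress
#' is purely configurational.
#'
#' @inheritParams compute_forces
#' @return list with the 3 x 3 `stress` tensor (eps / sigma^3) and the
#'   off-diagonal components `P_xy`, `P_xz`, `P_yz`.
#' @export
stress_tensor <- function(x, ff = ff_params()) {
  res <- compute_forces(x, ff)
  P <- res$stress
  list(stress = P, P_xy = P[1, 2], P_xz = P[1, 3], P_yz = P[2, 3])
}

#' Multiple-tau correlator
#'
#' Streaming autocorrelation accumulator on quasi-logarithmically spaced
#' lags: level 0 stores the raw samples (lags `0..p-1`), each higher level
#' stores `m`-block averages of the one below (lags `p/m..p-1` at that
#' level's coarser sampling). Feed samples with [mt_push()] and read the
#' correlation with [mt_correlation()].
#'
#' @param p points per level (default 16).
#' @param m block-averaging factor (default 2; must divide p).
#' @param max_levels hierarchy depth.
#' @return an object of class `multitau`.
#' @export
multitau <- function(p = 16L, m = 2L, max_levels = 32L) {
  stopifnot(p >= 2, m >= 2, p %% m == 0)
  structure(list(p = as.integer(p), m = as.integer(m),
                 max_levels = as.integer(max_levels),
                 buf = numeric(p * max_levels),
                 nfill = integer(max_levels),
                 acc = numeric(max_levels),
                 nacc = integer(max_levels),
                 corr = numeric(p * max_levels),
                 cnt = numeric(p * max_levels),
                 count = 0, sum = 0, sumsq = 0),
            class = "multitau")
}

#' Push samples into a multiple-tau correlator
#'
#' @param state a [multitau()] object.
#' @param x numeric vector of samples (must arrive at a fixed stride).
#' @return the updated correlator.
#' @export
mt_push <- function(state, x) {
  stopifnot(inherits(state, "multitau"))
  out <- cpp_mt_push(unclass(state), as.numeric(x))
  class(out) <- "multitau"
  out
}

#' Read the accumulated autocorrelation
#'
#' @param state a [multitau()] after pushing.
#' @param dt_sample time between successive pushed samples.
#' @param subtract_mean subtract the squared running mean (fluctuation
#'   autocorrelation); with `FALSE` the raw `<x(0) x(t)>` is returned.
#' @return data frame with lag time `t`, correlation `C` and the number of
#'   accumulated products `n`, sorted by `t`.
#' @export
mt_correlation <- function(state, dt_sample = 1, subtract_mean = TRUE) {
  stopifnot(inherits(state, "multitau"), state$count > 0)
  p <- state$p; m <- state$m
  mu2 <- if (subtract_mean) (state$sum / state$count)^2 else 0
  rows <- list()
  for (lvl in seq_len(state$max_levels) - 1L) {
    if (state$nfill[lvl + 1L] == 0L) break
    k0 <- if (lvl == 0L) 0L else p %/% m
    for (k in k0:(p - 1L)) {
      idx <- lvl * p + k + 1L
      if (state$cnt[idx] > 0) {
        rows[[length(rows) + 1L]] <- c(k * m^lvl * dt_sample,
                                       state$corr[idx] / state$cnt[idx] - mu2,
                                       state$cnt[idx])
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("t", "C", "n")
  out[order(out$t), , drop = FALSE]
}

#' @export
print.multitau <- function(x, ...) {
  cat(sprintf("Multiple-tau correlator: p = %d, m = %d, %g samples\n",
              x$p, x$m, x$count))
  invisible(x)
}

#' Integrate a shear relaxation modulus to a viscosity
#'
#' Trapezoidal integral of `G(t)` up to a cutoff at the noise floor: the
#' first lag where `G` drops below twice the standard deviation of its long
#' -time tail (or below zero). If `G` has not decayed into the floor within
#' the data, the integral is only a lower bound and is flagged.
#'
#' @param t lag times (tau_Br), increasing.
#' @param G modulus values (eps / sigma^3).
#' @return list with `eta`, `cutoff`, `flagged`.
#' @export
integrate_modulus <- function(t, G) {
  stopifnot(length(t) == length(G), length(t) >= 3, !is.unsorted(t))
  tail_idx <- seq.int(max(1L, floor(length(G) * 0.75)), length(G))
  floor_level <- max(0, 2 * stats::sd(G[tail_idx]))
  below <- which(G <= floor_level)
  below <- below[below > 1]
  flagged <- length(below) == 0
  cut <- if (flagged) length(G) else below[1]
  tt <- t[seq_len(cut)]; gg <- G[seq_len(cut)]
  eta <- sum(diff(tt) * (gg[-1] + gg[-length(gg)]) / 2)
  list(eta = eta, cutoff = t[cut], flagged = flagged)
}

#' Green-Kubo zero-shear viscosity
#'
#' Builds the shear relaxation modulus from the equilibrium fluctuations of
#' the three off-diagonal stress components,
#' `G(t) = (V / 3 k_B T) sum_ab <P_ab(0) P_ab(t)>`, via multiple-tau
#' correlators, and integrates it to the viscosity
#' `eta = int_0^cutoff G(t) dt`. The statistical error is estimated by
#' repeating the computation on contiguous blocks of the series.
#'
#' @param stress data frame with columns `Pxy`, `Pxz`, `Pyz` sampled at a
#'   fixed interval (e.g. the `stress` element of [bd_run()]).
#' @param V box volume (sigma^3).
#' @param temperature temperature (eps / k_B).
#' @param dt_sample sampling interval of the stress series (tau_Br).
#' @param p,m multiple-tau parameters.
#' @param n_blocks blocks for the error estimate.
#' @return an object of class `green_kubo`: `G` (data frame `t`, `G`),
#'   `eta` (k_B T tau_Br / sigma^3), `cutoff`, `eta_err`, `flagged`.
#' @export
green_kubo <- function(stress, V, temperature, dt_sample, p = 16L, m = 2L,
                       n_blocks = 4L) {
  comp <- c("Pxy", "Pxz", "Pyz")
  stopifnot(all(comp %in% names(stress)))
  build_G <- function(df) {
    cs <- lapply(comp, function(cc) {
      mt_correlation(mt_push(multitau(p, m), df[[cc]]), dt_sample)
    })
    tt <- cs[[1]]$t
    G <- (cs[[1]]$C + cs[[2]]$C + cs[[3]]$C) * V / (3 * temperature)
    data.frame(t = tt, G = G)
  }
  G <- build_G(stress)
  intg <- integrate_modulus(G$t, G$G)
  n <- nrow(stress)
  eta_err <- NA_real_
  if (n_blocks >= 2 && n >= n_blocks * 64) {
    bl <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
    etas <- vapply(bl, function(ix) {
      Gb <- build_G(stress[ix, , drop = FALSE])
      integrate_modulus(Gb$t, Gb$G)$eta
    }, numeric(1))
    eta_err <- stats::sd(etas) / sqrt(n_blocks)
  }
  structure(list(G = G, eta = intg$eta, cutoff = intg$cutoff,
                 eta_err = eta_err, flagged = intg$flagged,
                 V = V, temperature = temperature),
            class = "green_kubo")
}

#' @export
print.green_kubo <- function(x, ...) {
  cat(sprintf(
    "Green-Kubo viscosity: eta = %.4g%s k_BT tau_Br / sigma^3 (cutoff %.3g tau_Br)\n",
    x$eta, if (x$flagged) " (lower bound: G(t) not decayed)" else "",
    x$cutoff))
  if (is.finite(x$eta_err)) cat(sprintf("  block error: +/- %.2g\n", x$eta_err))
  invisible(x)
}

#' @export
plot.green_kubo <- function(x, ...) {
  pos <- x$G$G > 0 & x$G$t > 0
  graphics::plot(x$G$t[pos], x$G$G[pos], log = "xy", type = "l",
                 xlab = "t (tau_Br)", ylab = "G(t) (eps / sigma^3)", ...)
  graphics::abline(v = x$cutoff, lty = 3)
  invisible(x)
}
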