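#' Bonded fraction of patches
#'
#' `theta = 2 N_c / (N f)`: the fraction of sticky ends engaged in a bond.
#' Its steady-state temperature dependence is the melting curve of the gel.
#'
#' @param N_c number of patch-patch contacts.
#' @param N number of nanostars.
#' @param f valence (3).
#' @export
theta_fraction <- function(N_c, N, f = 3) {
  stopifnot(N > 0, f > 0)
  pmin(1, pmax(0, 2 * N_c / (N * f)))
}

#' Patch-patch contact graph of a configuration
#'
#' Edges connect stars whose patches are within `r_bond` of each other
#' (minimum image). Each patch can take part in at most one bond: when a
#' patch has several partners in range only the nearest counts (greedy
#' nearest-first matching), which enforces the single-bond-per-patch
#' bookkeeping of the valence-limited model.
#'
#' @param x an `ns_state` or a bead frame (see [compute_forces()] for the
#'   accepted fields).
#' @param r_bond bonding distance (sigma); default the patch cutoff
#'   `r0_m + 0.2 sigma`.
#' @return an object of class `contact_graph`: the bond table (`bonds`),
#'   the contact count `N_c`, per-star `degrees`, and the star count `N`.
#' @export
find_contacts <- function(x, r_bond = ff_params()$r_cut_patch) {
  fr <- as_bead_frame(x)
  is_patch <- fr$type_code == 2L
  ppos <- fr$positions[is_patch, , drop = FALSE]
  pmol <- fr$mol[is_patch]
  parm <- fr$arm[is_patch]
  bonds <- cpp_contacts(ppos, pmol, parm, fr$box_L, r_bond)
  n <- length(unique(fr$mol))
  deg <- tabulate(c(bonds$mol_a, bonds$mol_b), nbins = n)
  structure(list(bonds = bonds, N_c = nrow(bonds), degrees = deg, N = n,
                 r_bond = r_bond),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("Contact graph: N = %d stars, N_c = %d bonds, theta = %.3f\n",
              x$N, x$N_c, theta_fraction(x$N_c, x$N)))
  invisible(x)
}

#' Convert a contact graph to an igraph object
#'
#' @param graph a [find_contacts()] result.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  igraph::graph_from_data_frame(
    data.frame(from = graph$bonds$mol_a, to = graph$bonds$mol_b),
    directed = FALSE,
    vertices = data.frame(name = seq_len(graph$N)))
}

#' Degree histogram, components and largest-component fraction
#'
#' With valence 3 the degree of a star is 0, 1, 2 or 3. The connectivity of
#' the gel is summarised by `c_s`, the fraction of stars in the largest
#' connected component.
#'
#' @param graph a [find_contacts()] result.
#' @return list with `degree_hist` (named counts over 0..3), `c_s`,
#'   `component_sizes` (decreasing) and `n_components`.
#' @export
graph_metrics <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  dh <- tabulate(graph$degrees + 1L, nbins = 4L)
  names(dh) <- 0:3
  list(degree_hist = dh,
       c_s = max(comp$csize) / graph$N,
       component_sizes = sort(comp$csize, decreasing = TRUE),
       n_components = comp$no)
}

#' Melting curve and melting temperature
#'
#' Interpolates the steady-state bonded fraction `<theta>(T)` linearly to
#' find the melting temperature `T_m` where `<theta> = 0.5`.
#'
#' @param data data frame with columns `temperature`, `theta` and optionally
#'   `theta_se` (standard errors).
#' @return an object of class `melting_curve` with the table and `T_m`.
#' @export
melting_curve <- function(data) {
  stopifnot(is.data.frame(data), all(c("temperature", "theta") %in%
                                     names(data)), nrow(data) >= 2)
  data <- data[order(data$temperature), , drop = FALSE]
  th <- data$theta
  if (any(th < 0 | th > 1)) stop("theta must lie in [0, 1]", call. = FALSE)
  s <- th - 0.5
  k <- which(s[-length(s)] * s[-1] <= 0)
  if (length(k) == 0) {
    stop(sprintf(
      "no theta = 0.5 crossing: observed theta in [%.3f, %.3f] over T in [%g, %g]",
      min(th), max(th), min(data$temperature), max(data$temperature)),
      call. = FALSE)
  }
  k <- k[1]
  t1 <- data$temperature[k]; t2 <- data$temperature[k + 1]
  T_m <- if (th[k] == th[k + 1]) (t1 + t2) / 2 else {
    t1 + (0.5 - th[k]) * (t2 - t1) / (th[k + 1] - th[k])
  }
  structure(list(table = data, T_m = T_m), class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("Melting curve over %d temperatures: T_m = %.4f eps/k_B\n",
              nrow(x$table), x$T_m))
  invisible(x)
}

#' @export
plot.melting_curve <- function(x, ...) {
  graphics::plot(x$table$temperature, x$table$theta, type = "b", pch = 19,
                 xlab = "T (eps / k_B)", ylab = expression(theta), ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$T_m, lty = 3)
  invisible(x)
}

#' Network relaxation time from the contact-count series
#'
#' The characteristic reconfiguration time of the gel is the decay time of
#' the normalized fluctuation autocorrelation of `N_c(t)`:
#' `C(t) = <dNc(t0) dNc(t0+t)> / <dNc^2>`. `tau_c` is obtained by least
#' squares on `exp(-t / tau_c)` over the window where `C` is still above
#' `c_min`. If `C` never decays below `c_min` within the series the value is
#' a lower bound (`flagged = TRUE`, frozen network).
#'
#' @param n_c contact-count time series (stationary segment; drop the
#'   post-quench transient before calling).
#' @param dt_sample sampling interval of the series (tau_Br).
#' @param c_min lower edge of the fit window.
#' @param max_lag_frac largest lag used, as a fraction of the series length.
#' @return list with `tau_c` (tau_Br), `flagged`, and the `acf` data frame.
#' @export
relaxation_time <- function(n_c, dt_sample, c_min = 0.05,
                            max_lag_frac = 0.5) {
  n <- length(n_c)
  stopifnot(n >= 10, dt_sample > 0)
  if (stats::var(n_c) == 0) {
    return(list(tau_c = Inf, flagged = TRUE,
                acf = data.frame(t = 0, C = 1)))
  }
  lag_max <- max(2L, floor(n * max_lag_frac))
  ac <- stats::acf(n_c, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  tt <- (seq_along(ac) - 1) * dt_sample
  below <- which(ac < c_min)
  flagged <- length(below) == 0
  w <- seq_len(if (flagged) length(ac) else max(2L, below[1] - 1))
  fit <- stats::optimize(function(lt) {
    sum((ac[w] - exp(-tt[w] / exp(lt)))^2)
  }, interval = log(c(dt_sample / 10, max(tt) * 100)))
  tau <- exp(fit$minimum)
  list(tau_c = tau, flagged = flagged,
       acf = data.frame(t = tt, C = ac))
}

#' Arrhenius fit of the relaxation time
#'
#' Fits `tau_c(T) = a exp(E_a / k_B T)` by linear regression of `log tau_c`
#' on `1 / T`. Temperatures in the low-T plateau (where the network is
#' frozen and tau_c is only a lower bound) should be excluded by the caller.
#'
#' @param temperature temperatures (eps / k_B), at least 3.
#' @param tau_c relaxation times (tau_Br).
#' @return an object of class `arrhenius_fit` with `a` (tau_Br), `E_a`
#'   (k_B T units), the fit `covariance` and the underlying `lm` fit.
#' @export
arrhenius_fit <- function(temperature, tau_c) {
  stopifnot(length(temperature) == length(tau_c))
  if (length(temperature) < 3) {
    stop("need at least 3 temperatures in the decaying regime", call. = FALSE)
  }
  stopifnot(all(tau_c > 0))
  invT <- 1 / temperature
  fit <- stats::lm(log(tau_c) ~ invT)
  co <- stats::coef(fit)
  structure(list(a = exp(unname(co[1])), E_a = unname(co[2]),
                 covariance = stats::vcov(fit), fit = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  se <- sqrt(diag(x$covariance))
  cat(sprintf(
    "Arrhenius fit: tau_c = a exp(E_a / T), a = %.3g tau_Br, E_a = %.3g (+/- %.2g) k_BT\n",
    x$a, x$E_a, se[2]))
  invisible(x)
}

#' Mean squared displacement of nanostar centres
#'
#' Time- and ensemble-averaged `MSD(t) = <[r(t0 + t) - r(t0)]^2>` over all
#' stars and time origins, on a quasi-logarithmic lag grid. Input must be
#' unwrapped coordinates (see [unwrapped_centers()]); wrapped input is
#' detected through jumps larger than half the box and rejected.
#'
#' @param centers array `[frame, star, axis]` of unwrapped positions, or an
#'   `ns_run` with saved frames.
#' @param times frame times (tau_Br); taken from the run if omitted.
#' @param box_L if given, used to detect wrapped input.
#' @param n_lags number of lag points.
#' @return data frame with `t` (lag, tau_Br) and `msd` (sigma^2).
#' @export
msd <- function(centers, times = NULL, box_L = NULL, n_lags = 40) {
  if (inherits(centers, "ns_run")) {
    run <- centers
    if (is.null(box_L)) box_L <- run$state$box_L
    if (is.null(times)) times <- run$frames$times
    centers <- unwrapped_centers(run)
  }
  stopifnot(length(dim(centers)) == 3)
  nf <- dim(centers)[1]
  stopifnot(nf >= 2, !is.null(times), length(times) == nf)
  if (!is.null(box_L)) {
    jumps <- abs(centers[-1, , , drop = FALSE] -
                 centers[-nf, , , drop = FALSE])
    if (any(jumps > box_L / 2)) {
      stop("wrapped coordinates detected (jump > L/2); unwrap with image ",
           "flags first", call. = FALSE)
    }
  }
  lags <- unique(round(exp(seq(log(1), log(nf - 1), length.out = n_lags))))
  out <- vapply(lags, function(l) {
    d <- centers[(1 + l):nf, , , drop = FALSE] -
         centers[1:(nf - l), , , drop = FALSE]
    mean(apply(d^2, c(1, 2), sum))
  }, numeric(1))
  data.frame(t = (times[2] - times[1]) * lags, msd = out)
}

#' Radial distribution function of the nanostar cores
#'
#' Standard periodic-box pair-count g(r): histogrammed minimum-image core
#' distances normalized by the ideal-gas shell counts, averaged over frames.
#'
#' @param frames list of n x 3 core-position matrices (or one matrix), or an
#'   `ns_run` with saved frames (cores = centres for the rigid template).
#' @param box_L box edge (sigma).
#' @param bin_w bin width (sigma); 0.1 resolves the close peak pairs of the
#'   non-planar gel.
#' @param r_max largest distance, at most L/2.
#' @return data frame with bin centres `r` and `g`.
#' @export
rdf <- function(frames, box_L = NULL, bin_w = 0.1, r_max = NULL) {
  if (inherits(frames, "ns_run")) {
    run <- frames
    if (is.null(box_L)) box_L <- run$state$box_L
    cen <- run$frames$centers
    frames <- lapply(seq_len(dim(cen)[1]), function(i) cen[i, , ])
  }
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(!is.null(box_L))
  if (is.null(r_max)) r_max <- box_L / 2
  if (r_max > box_L / 2) {
    stop("r_max must not exceed half the box edge", call. = FALSE)
  }
  nbins <- floor(r_max / bin_w)
  counts <- numeric(nbins)
  n <- nrow(frames[[1]])
  for (f in frames) counts <- counts + cpp_pair_hist(as.matrix(f), box_L,
                                                     bin_w, nbins)
  counts <- counts / length(frames)
  edges <- (0:nbins) * bin_w
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  ideal <- n * (n - 1) / 2 * shell / box_L^3
  data.frame(r = edges[-(nbins + 1)] + bin_w / 2, g = counts / ideal)
}

#' Bending-angle distribution of bonded arms
#'
#' Pools the effective bending angle phi over every bond of every supplied
#' frame (see [bending_angle()] for the definition) and histograms it in
#' 5-degree bins, weighting nothing: the raw distribution as sampled.
#'
#' @param run an `ns_run` with saved frames, or a list of `ns_state`s.
#' @param frame_idx which frames to use (default all).
#' @param r_bond bonding distance.
#' @param bin_w histogram bin width (degrees).
#' @return list with the pooled `phi` values (degrees), `mean`, `mode`
#'   (centre of the fullest bin) and the `hist` data frame.
#' @export
phi_distribution <- function(run, frame_idx = NULL,
                             r_bond = ff_params()$r_cut_patch,
                             bin_w = 5) {
  states <- if (inherits(run, "ns_run")) {
    if (is.null(frame_idx)) frame_idx <- seq_along(run$frames$times)
    lapply(frame_idx, function(i) run_frame_state(run, i))
  } else run
  phis <- unlist(lapply(states, function(st) {
    g <- find_contacts(st, r_bond)
    if (g$N_c == 0) return(numeric(0))
    axes_all <- lapply(seq_len(nrow(st$centers)), function(i) {
      st$template$arm_axes %*% t(quat_to_matrix(st$quats[i, ]))
    })
    vapply(seq_len(g$N_c), function(b) {
      ea <- axes_all[[g$bonds$mol_a[b]]][g$bonds$arm_a[b], ]
      eb <- axes_all[[g$bonds$mol_b[b]]][g$bonds$arm_b[b], ]
      compute_alpha(ea, -eb)
    }, numeric(1))
  }))
  if (length(phis) == 0) {
    return(list(phi = numeric(0), mean = NaN, mode = NaN,
                hist = data.frame(phi = numeric(0), count = numeric(0))))
  }
  breaks <- seq(0, 180, by = bin_w)
  h <- graphics::hist(phis, breaks = breaks, plot = FALSE)
  list(phi = phis, mean = mean(phis),
       mode = h$mids[which.max(h$counts)],
       hist = data.frame(phi = h$mids, count = h$counts))
}

# Rebuild an ns_state from a saved frame of a run.
run_frame_state <- function(run, i) {
  st <- run$state
  st$centers <- run$frames$centers[i, , , drop = TRUE]
  st$quats <- run$frames$quats[i, , , drop = TRUE]
  st$images <- run$frames$images[i, , , drop = TRUE]
  storage.mode(st$images) <- "integer"
  st$time <- run$frames$times[i]
  st
}
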