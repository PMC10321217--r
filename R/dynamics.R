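#' Volume fraction of a nanostar system
#'
#' Each star carries 7 finite-size beads of diameter sigma (the patch sites
#' are volumeless), so `rho = N * 7 * (pi/6) sigma^3 / L^3`. The reference
#' gel conditions are N = 175 in an L = 40 sigma box (rho = 0.01) and
#' N = 1050 at the overlap concentration (rho = 0.06).
#'
#' @param N number of nanostars.
#' @param box_L cubic box edge (sigma).
#' @export
volume_fraction <- function(N, box_L) {
  stopifnot(N >= 0, box_L > 0)
  N * 7 * (pi / 6) / box_L^3
}

#' Construct a simulation state
#'
#' A state is the full configuration of N rigid nanostars: wrapped centre
#' positions, unit orientation quaternions, periodic image flags, box size,
#' temperature and clock.
#'
#' @param template an [ns_template()].
#' @param centers N x 3 matrix of centre positions (sigma).
#' @param quats N x 4 matrix of unit quaternions (w, x, y, z); default
#'   identity.
#' @param box_L cubic box edge (sigma).
#' @param temperature temperature in epsilon / k_B.
#' @param images N x 3 integer periodic image flags; default 0.
#' @param time simulation clock (tau_Br).
#' @return an object of class `ns_state`.
#' @export
sim_state <- function(template, centers, quats = NULL, box_L,
                      temperature = 1, images = NULL, time = 0) {
  stopifnot(inherits(template, "ns_template"))
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, box_L > 0, temperature > 0)
  n <- nrow(centers)
  if (is.null(quats)) quats <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  quats <- as.matrix(quats)
  stopifnot(nrow(quats) == n, ncol(quats) == 4)
  quats <- quats / sqrt(rowSums(quats^2))
  if (is.null(images)) images <- matrix(0L, n, 3)
  storage.mode(images) <- "integer"
  wrapped <- centers - floor(centers / box_L) * box_L
  images <- images + matrix(as.integer(floor(centers / box_L)), n, 3)
  structure(
    list(template = template, centers = wrapped, quats = quats,
         images = images, box_L = box_L, temperature = temperature,
         time = time),
    class = "ns_state")
}

#' @export
print.ns_state <- function(x, ...) {
  n <- nrow(x$centers)
  cat(sprintf(
    "Nanostar state: N = %d, L = %g sigma, T = %g eps/k_B, t = %g tau_Br\n",
    n, x$box_L, x$temperature, x$time))
  cat(sprintf("  d_p = %g, volume fraction rho = %.4f\n",
              x$template$d_p_target, volume_fraction(n, x$box_L)))
  invisible(x)
}

#' Brownian-dynamics parameters
#'
#' Overdamped (inertia-free) rigid-body dynamics in reduced units: the
#' single-bead diffusion constant defines the time unit, `D = sigma^2 /
#' tau_Br = 1`. A 10-bead star then gets `D_t = D / 7` (the 7 finite beads
#' carry the drag, isotropic approximation) and `D_r = 3 D_t / sigma_h^2`
#' with hydrodynamic radius `sigma_h = 2.5 sigma` (the arm reach). The drift
#' mobility follows from fluctuation-dissipation, `mu = D / (k_B T)`.
#'
#' @param dt time step (tau_Br).
#' @param D_t translational diffusion coefficient (sigma^2 / tau_Br).
#' @param D_r rotational diffusion coefficient (1 / tau_Br).
#' @param neighbor_skin Verlet-list skin (sigma); the star-pair list is
#'   rebuilt when any centre has moved more than half the skin.
#' @export
bd_params <- function(dt = 1e-4, D_t = 1 / 7, D_r = 3 * (1 / 7) / 2.5^2,
                      neighbor_skin = 1.0) {
  stopifnot(dt > 0, D_t > 0, D_r > 0, neighbor_skin > 0)
  structure(list(dt = dt, D_t = D_t, D_r = D_r,
                 neighbor_skin = neighbor_skin),
            class = "bd_params")
}

#' Run overdamped rigid-body Brownian dynamics
#'
#' Euler-Maruyama integration of N rigid nanostars: centres advance by
#' `(D_t / k_B T) F dt` plus Gaussian noise of variance `2 D_t dt` per axis;
#' orientations rotate by `(D_r / k_B T) Tq dt` plus angular noise of
#' variance `2 D_r dt`, where F and Tq are the net force and torque from the
#' bead-level pair interactions. A step whose largest centre displacement
#' exceeds 0.1 sigma is redone with dt halved (counted in `n_halved`).
#' Trajectories are bit-reproducible for a fixed seed.
#'
#' @param state an [sim_state()].
#' @param ff an [ff_params()].
#' @param dyn a [bd_params()].
#' @param n_steps number of time steps.
#' @param record_every cadence (steps) for the observable series (time,
#'   energy, contact count, bonded fraction theta, off-diagonal stress).
#' @param stress_every cadence for the fine-grained stress series used by
#'   the Green-Kubo pipeline; 0 disables it.
#' @param save_frames keep centre/orientation frames at the record cadence.
#' @param r_bond patch-patch contact distance for N_c (defaults to the patch
#'   cutoff).
#' @param observers optional named list of callbacks `function(state)`
#'   evaluated on every recorded frame; their results are returned as
#'   per-frame lists under `observed` (frames are retained to support
#'   this).
#' @param seed integer seed for the thermal noise (required: runs are
#'   deterministic functions of it).
#' @return an object of class `ns_run`: the final `state`, `series` and
#'   `stress` data frames, optional `frames` (arrays `[frame, star, axis]`),
#'   and integrator counters.
#' @export
bd_run <- function(state, ff = ff_params(), dyn = bd_params(),
                   n_steps, record_every = 1000L, stress_every = 0L,
                   save_frames = FALSE, r_bond = NULL, observers = NULL,
                   seed) {
  stopifnot(inherits(state, "ns_state"), inherits(ff, "ns_ff"),
            inherits(dyn, "bd_params"), n_steps >= 0)
  if (missing(seed)) stop("an integer seed is required", call. = FALSE)
  if (is.null(r_bond)) r_bond <- ff$r_cut_patch
  if (!is.null(observers)) {
    stopifnot(is.list(observers), all(vapply(observers, is.function, TRUE)))
    save_frames <- TRUE
  }
  # the star-pair minimum-image convention needs the box to exceed twice
  # the pair interaction reach plus the list skin
  reach <- 2 * (2 * 2.5 + max(ff$r_cut_patch, 2^(1 / 6))) +
    2 * dyn$neighbor_skin
  if (state$box_L < reach) {
    stop(sprintf(
      "box_L = %g sigma is too small for the pair bookkeeping: need >= %.2f",
      state$box_L, reach), call. = FALSE)
  }
  tpl <- state$template
  res <- cpp_run_bd(state$centers, state$quats, state$images,
                    tpl$bead_positions, template_type_codes(tpl),
                    state$box_L, state$temperature, ff_to_cpp(ff),
                    dyn$D_t, dyn$D_r, dyn$dt,
                    as.integer(n_steps), as.integer(record_every),
                    as.integer(stress_every), isTRUE(save_frames),
                    r_bond, dyn$neighbor_skin, state$time, as.double(seed))
  n <- nrow(state$centers)
  out_state <- state
  out_state$centers <- res$centers
  out_state$quats <- res$quats
  out_state$images <- res$images
  out_state$time <- res$time
  series <- as.data.frame(res$series)
  series$theta <- theta_fraction(series$n_contacts, n, tpl$f)
  run <- list(state = out_state,
              series = series,
              stress = as.data.frame(res$stress),
              n_rebuild = res$n_rebuild, n_halved = res$n_halved,
              n_overlap = res$n_overlap,
              dt = dyn$dt, seed = seed, ff = ff, dyn = dyn)
  if (isTRUE(save_frames)) {
    run$frames <- list(centers = res$frame_centers,
                       quats = res$frame_quats,
                       images = res$frame_images,
                       times = series$time)
  }
  run <- structure(run, class = "ns_run")
  if (!is.null(observers)) {
    run$observed <- lapply(observers, function(f) {
      lapply(seq_along(run$frames$times),
             function(i) f(run_frame_state(run, i)))
    })
  }
  run
}

#' @export
print.ns_run <- function(x, ...) {
  s <- x$series
  cat(sprintf("BD run: %d recorded points, t = %g .. %g tau_Br (seed %s)\n",
              nrow(s), s$time[1], s$time[nrow(s)], format(x$seed)))
  cat(sprintf("  final theta = %.3f, N_c = %d, energy = %.2f eps\n",
              s$theta[nrow(s)], s$n_contacts[nrow(s)], s$energy[nrow(s)]))
  if (x$n_halved > 0) {
    cat(sprintf("  note: %d step(s) needed dt halving\n", x$n_halved))
  }
  invisible(x)
}

#' Advance a state by a single BD step
#'
#' @inheritParams bd_run
#' @return the updated `ns_state`.
#' @export
bd_step <- function(state, ff = ff_params(), dyn = bd_params(), seed) {
  bd_run(state, ff, dyn, n_steps = 1L, record_every = 0L, seed = seed)$state
}

#' Unwrapped centre coordinates of a run's frames
#'
#' @param run an [bd_run()] result with `save_frames = TRUE`.
#' @return array `[frame, star, axis]` of unwrapped positions.
#' @export
unwrapped_centers <- function(run) {
  stopifnot(inherits(run, "ns_run"), !is.null(run$frames))
  run$frames$centers + run$frames$images * run$state$box_L
}
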