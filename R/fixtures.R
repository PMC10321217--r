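#' Deterministic test configurations
#'
#' Builds small reference configurations used throughout the tests and
#' examples:
#' \describe{
#'   \item{`dimer`}{two planar stars bonded arm-to-arm at the Morse minimum;
#'     the core-core distance is `2 * 2.5 sigma + r0_m` (about 5 sigma, the
#'     position of the first peak of the gel's radial distribution
#'     function).}
#'   \item{`six_ring`}{a closed planar ring of six stars whose consecutive
#'     arms are bonded with zero bending angle; it has exactly 6 contacts
#'     and every star has degree 2.}
#'   \item{`gas`}{N stars at seeded random non-overlapping poses with no
#'     patch pair within the bonding cutoff: the unbonded starting point of
#'     a quench.}
#' }
#'
#' @param name one of `"dimer"`, `"six_ring"`, `"gas"`.
#' @param N number of stars (gas only).
#' @param box_L cubic box edge (sigma).
#' @param d_p planarity of the template (gas only; dimer and ring are planar
#'   constructions).
#' @param ff force field, used for the bond-distance geometry.
#' @param temperature stored in the state.
#' @param seed RNG seed (gas only).
#' @return an `ns_state`.
#' @export
make_fixture <- function(name = c("dimer", "six_ring", "gas"), N = 10,
                         box_L = 40, d_p = 0, ff = ff_params(),
                         temperature = 1, seed = 1) {
  name <- match.arg(name)
  switch(name,
    dimer = fixture_dimer(box_L, ff, temperature),
    six_ring = fixture_six_ring(box_L, ff, temperature),
    gas = fixture_gas(N, box_L, d_p, ff, temperature, seed))
}

fixture_dimer <- function(box_L, ff, temperature) {
  tpl <- ns_template(0)
  d <- 2 * tpl$patch_offset + ff$r0_m
  centers <- rbind(c(box_L / 2 - d / 2, box_L / 2, box_L / 2),
                   c(box_L / 2 + d / 2, box_L / 2, box_L / 2))
  # star 1 arm 1 along +x; star 2 rotated pi about z so its arm 1 faces -x
  quats <- rbind(c(1, 0, 0, 0), quat_from_axis_angle(c(0, 0, 1), pi))
  sim_state(tpl, centers, quats, box_L, temperature)
}

fixture_six_ring <- function(box_L, ff, temperature) {
  tpl <- ns_template(0)
  s <- 2 * tpl$patch_offset + ff$r0_m    # bonded core-core distance
  rhex <- s                              # hexagon circumradius = side
  th <- (0:5) * pi / 3
  centers <- cbind(box_L / 2 + rhex * cos(th),
                   box_L / 2 + rhex * sin(th),
                   box_L / 2)
  # arm 1 of star k points along the edge towards star k+1
  quats <- t(vapply(th + 2 * pi / 3,
                    function(a) quat_from_axis_angle(c(0, 0, 1), a),
                    numeric(4)))
  sim_state(tpl, centers, quats, box_L, temperature)
}

fixture_gas <- function(N, box_L, d_p, ff, temperature, seed) {
  stopifnot(N >= 1)
  tpl <- ns_template(d_p)
  rng <- local_rng(seed)
  centers <- matrix(NA_real_, N, 3)
  quats <- matrix(NA_real_, N, 4)
  beads_all <- NULL
  patches_all <- NULL
  placed <- 0L
  tries <- 0L
  while (placed < N) {
    tries <- tries + 1L
    if (tries > 2000L * N) {
      stop("could not place ", N, " non-overlapping stars in a box of ",
           box_L, " sigma", call. = FALSE)
    }
    cen <- stats::runif(3, 0, box_L)
    qt <- random_quats(1)[1, ]
    beads <- sweep(tpl$bead_positions %*% t(quat_to_matrix(qt)), 2, cen, "+")
    ok <- TRUE
    if (placed > 0L) {
      finite <- beads[1:7, , drop = FALSE]
      dmin <- min_image_min_dist(finite, beads_all, box_L)
      if (dmin < 1) ok <- FALSE
      if (ok) {
        pmin <- min_image_min_dist(beads[8:10, , drop = FALSE], patches_all,
                                   box_L)
        if (pmin < ff$r_cut_patch) ok <- FALSE
      }
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cen
      quats[placed, ] <- qt
      beads_all <- rbind(beads_all, beads[1:7, , drop = FALSE])
      patches_all <- rbind(patches_all, beads[8:10, , drop = FALSE])
    }
  }
  rng$restore()
  sim_state(tpl, centers, quats, box_L, temperature)
}

# minimum over all cross pairs of minimum-image distances
min_image_min_dist <- function(a, b, box_L) {
  dmin <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ], "-")
    d <- d - box_L * round(d / box_L)
    dmin <- min(dmin, sqrt(min(rowSums(d^2))))
  }
  dmin
}

# Seed-scoped RNG that restores the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
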