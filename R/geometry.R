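#' Build a rigid trivalent nanostar template
#'
#' Constructs the 10-bead rigid body representing one trivalent DNA nanostar:
#' a core bead at the local origin, two excluded-volume beads per arm at 1 and
#' 2 sigma along each arm axis, and a massless attractive patch site at
#' 2.5 sigma (the edge of the outermost bead). The three arm axes make polar
#' angle `psi = acos(d_p)` with the template symmetry axis and are 120 degrees
#' apart in azimuth, so the planarity [compute_dp()] of the template equals
#' `d_p` by construction: `d_p = 0` is a flat Y with 120-degree inter-arm
#' angles, and as `d_p -> 1` the arms collapse onto a common axis.
#'
#' @param d_p target planarity, a dimensionless number in `[0, 1)`.
#' @return An object of class `ns_template`: a list with `bead_positions`
#'   (10 x 3, sigma), `types` (character: CORE/ARM/PATCH), `arm_axes`
#'   (3 x 3, unit rows), `arm_of_bead`, `d_p_target`, `f = 3`, `sigma = 1`
#'   and `patch_offset = 2.5`.
#' @examples
#' tpl <- ns_template(0.6)
#' compute_dp(tpl$arm_axes)
#' @export
ns_template <- function(d_p = 0) {
  stopifnot(is.numeric(d_p), length(d_p) == 1L, is.finite(d_p))
  if (d_p < 0 || d_p >= 1) {
    stop("d_p must lie in [0, 1): at d_p = 1 the three arms are colinear ",
         "and the template is degenerate", call. = FALSE)
  }
  psi <- acos(d_p)
  az <- c(0, 2, 4) * pi / 3
  axes <- cbind(sin(psi) * cos(az), sin(psi) * sin(az), rep(cos(psi), 3))
  rownames(axes) <- paste0("arm", 1:3)

  pos <- matrix(0, 10, 3)
  types <- c("CORE", rep("ARM", 6), rep("PATCH", 3))
  arm_of_bead <- c(NA, 1L, 1L, 2L, 2L, 3L, 3L, 1L, 2L, 3L)
  for (k in 1:3) {
    pos[2 * k, ] <- axes[k, ]            # 1 sigma
    pos[2 * k + 1, ] <- 2 * axes[k, ]    # 2 sigma
    pos[7 + k, ] <- 2.5 * axes[k, ]      # patch site
  }

  structure(
    list(bead_positions = pos, types = types, arm_axes = axes,
         arm_of_bead = arm_of_bead, d_p_target = d_p, f = 3L,
         sigma = 1, patch_offset = 2.5),
    class = "ns_template")
}

#' @export
print.ns_template <- function(x, ...) {
  cat("Rigid nanostar template (f = 3, 10 beads)\n")
  cat(sprintf("  planarity d_p = %.4f  (polar angle %.2f deg)\n",
              x$d_p_target, acos(x$d_p_target) * 180 / pi))
  a <- compute_alpha(x$arm_axes[1, ], x$arm_axes[2, ])
  cat(sprintf("  inter-arm angle alpha = %.3f deg\n", a))
  invisible(x)
}

# integer bead type codes used by the compiled core
template_type_codes <- function(template) {
  match(template$types, c("CORE", "ARM", "PATCH")) - 1L
}

#' Planarity of a nanostar from its three arm axes
#'
#' The planarity collective variable `d_p` is the unsigned distance from the
#' core of the molecule (the origin of the arm vectors) to the plane through
#' the tips of the three *normalized* arm vectors. A flat Y gives 0; nearly
#' colinear arms give values approaching 1.
#'
#' @param arm_axes a 3 x 3 matrix whose rows are the arm direction vectors
#'   (normalized internally if needed).
#' @param tol degeneracy tolerance on the norm of the plane normal.
#' @return the planarity, a number in `[0, 1]`.
#' @seealso [dp_symmetric_limit()] for the closed form of the symmetric case.
#' @export
compute_dp <- function(arm_axes, tol = 1e-8) {
  stopifnot(is.matrix(arm_axes), all(dim(arm_axes) == c(3, 3)))
  nrm <- sqrt(rowSums(arm_axes^2))
  if (any(nrm < tol)) stop("arm vectors must be non-zero", call. = FALSE)
  e <- arm_axes / nrm
  n <- cross3(e[2, ] - e[1, ], e[3, ] - e[1, ])
  nn <- sqrt(sum(n^2))
  if (nn < tol) {
    stop("degenerate geometry: the three arm-vector tips are colinear or ",
         "coincident; for a symmetric template use dp_symmetric_limit(psi)",
         call. = FALSE)
  }
  abs(sum(n * e[1, ])) / nn
}

#' Symmetric-limit planarity
#'
#' For three arms at equal polar angle `psi` from a common axis (120 degrees
#' apart in azimuth) the planarity reduces to `cos(psi)`. Useful where the
#' general plane fit in [compute_dp()] is degenerate (nearly colinear tips).
#'
#' @param psi polar angle in radians.
#' @export
dp_symmetric_limit <- function(psi) cos(psi)

#' Angle between two arm axes
#'
#' `alpha_ij = acos(e_i . e_j)` in degrees. Non-unit inputs are normalized
#' with a warning.
#'
#' @param e_i,e_j arm direction vectors (length 3).
#' @return angle in degrees, in `[0, 180]`.
#' @export
compute_alpha <- function(e_i, e_j) {
  stopifnot(length(e_i) == 3, length(e_j) == 3)
  ni <- sqrt(sum(e_i^2)); nj <- sqrt(sum(e_j^2))
  if (abs(ni - 1) > 1e-8 || abs(nj - 1) > 1e-8) {
    warning("non-unit arm vectors; normalizing")
  }
  d <- sum(e_i * e_j) / (ni * nj)
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Closed-form inter-arm angle of a symmetric template
#'
#' For the symmetric template all three pairwise angles are equal:
#' `alpha(d_p) = acos((3 d_p^2 - 1) / 2)`, decreasing from 120 degrees at
#' `d_p = 0` to 0 as `d_p -> 1`.
#'
#' @param d_p planarity in `[0, 1]`.
#' @return angle in degrees.
#' @export
alpha_of_dp <- function(d_p) acos((3 * d_p^2 - 1) / 2) * 180 / pi

#' Place a nanostar template in the simulation box
#'
#' @param template an [ns_template()].
#' @param center length-3 position of the core (sigma).
#' @param quat unit quaternion `(w, x, y, z)` giving the orientation.
#' @return an object of class `placed_star` with world-frame `beads`,
#'   `arm_axes` and `patch_positions`.
#' @export
placed_star <- function(template, center = c(0, 0, 0), quat = c(1, 0, 0, 0)) {
  stopifnot(inherits(template, "ns_template"), length(center) == 3,
            length(quat) == 4)
  quat <- quat / sqrt(sum(quat^2))
  R <- quat_to_matrix(quat)
  beads <- sweep(template$bead_positions %*% t(R), 2, center, "+")
  axes <- template$arm_axes %*% t(R)
  structure(list(template = template, center = center, quat = quat,
                 beads = beads, arm_axes = axes,
                 patch_positions = beads[8:10, , drop = FALSE]),
            class = "placed_star")
}

#' Bending angle between the bonded arms of two nanostars
#'
#' Two hybridized arms define an effective bending angle `phi`: the angle
#' between the arm axis of the first star and the *reversed* arm axis of its
#' partner, so perfectly aligned end-to-end arms give `phi = 0` and any
#' kink at the joint gives `phi > 0`.
#'
#' @param star_a,star_b [placed_star()] objects.
#' @param arm_a,arm_b arm indices (1..3) of the bonded arms.
#' @param r_bond patch-patch distance below which the arms count as bonded.
#' @param box_L periodic box edge used for the bond check; `Inf` for open
#'   boundaries.
#' @param check verify the named arms are actually patch-bonded.
#' @return the bending angle in degrees.
#' @export
bending_angle <- function(star_a, arm_a, star_b, arm_b,
                          r_bond = ff_params()$r_cut_patch, box_L = Inf, check = TRUE) {
  stopifnot(inherits(star_a, "placed_star"), inherits(star_b, "placed_star"),
            arm_a %in% 1:3, arm_b %in% 1:3)
  if (check) {
    d <- star_a$patch_positions[arm_a, ] - star_b$patch_positions[arm_b, ]
    if (is.finite(box_L)) d <- d - box_L * round(d / box_L)
    if (sqrt(sum(d^2)) >= r_bond) {
      stop(sprintf(
        "arm %d of star_a and arm %d of star_b are not bonded (patch distance %.3f >= r_bond %.3f)",
        arm_a, arm_b, sqrt(sum(d^2)), r_bond), call. = FALSE)
    }
  }
  compute_alpha(star_a$arm_axes[arm_a, ], -star_b$arm_axes[arm_b, ])
}

# ---- small vector helpers -------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
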