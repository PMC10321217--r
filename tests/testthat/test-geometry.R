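test_that("template construction and planarity round-trip on [0, 0.999]", {
  for (dp in c(0, 0.1, 0.3, 0.6, 0.9, 0.99, 0.999)) {
    tpl <- ns_template(dp)
    expect_equal(compute_dp(tpl$arm_axes), dp, tolerance = 1e-9)
    # bead placement: core at origin, arm beads at 1 and 2 sigma, patch at 2.5
    expect_equal(unname(tpl$bead_positions[1, ]), c(0, 0, 0))
    for (k in 1:3) {
      ax <- tpl$arm_axes[k, ]
      expect_equal(unname(tpl$bead_positions[2 * k, ]), unname(ax),
                   tolerance = 1e-12)
      expect_equal(unname(tpl$bead_positions[2 * k + 1, ]), unname(2 * ax),
                   tolerance = 1e-12)
      expect_equal(unname(tpl$bead_positions[7 + k, ]), unname(2.5 * ax),
                   tolerance = 1e-12)
    }
    # three-fold symmetry about z: rotating arm 1 by 120 deg gives arm 2
    R120 <- nanostargel:::quat_to_matrix(
      nanostargel:::quat_from_axis_angle(c(0, 0, 1), 2 * pi / 3))
    expect_equal(as.numeric(R120 %*% tpl$arm_axes[1, ]),
                 unname(tpl$arm_axes[2, ]), tolerance = 1e-12)
  }
  expect_error(ns_template(1), "d_p")
  expect_error(ns_template(-0.1), "d_p")
})

test_that("inter-arm angles follow the closed form and the brute-force oracle", {
  # planar Y: all three pairwise angles are 120 degrees
  tpl0 <- ns_template(0)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(compute_alpha(tpl0$arm_axes[pair[1], ],
                               tpl0$arm_axes[pair[2], ]), 120,
                 tolerance = 1e-9)
  }
  # d_p = 0.6: brute-force construction oracle (tilted unit vectors)
  ax <- symmetric_axes(acos(0.6))
  oracle_alpha <- acos(sum(ax[1, ] * ax[2, ])) * 180 / pi
  expect_equal(oracle_alpha, 87.7075572, tolerance = 1e-6)
  tpl6 <- ns_template(0.6)
  expect_equal(compute_alpha(tpl6$arm_axes[1, ], tpl6$arm_axes[2, ]),
               oracle_alpha, tolerance = 1e-9)
  expect_equal(alpha_of_dp(0.6), oracle_alpha, tolerance = 1e-9)
  # alpha decreases monotonically to 0 as d_p -> 1
  dps <- seq(0, 0.999, length.out = 50)
  alphas <- alpha_of_dp(dps)
  expect_true(all(diff(alphas) < 0))
  expect_lt(alpha_of_dp(0.999), 5)
  # identical vectors
  expect_equal(compute_alpha(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_warning(compute_alpha(c(2, 0, 0), c(0, 1, 0)), "normaliz")
})

test_that("compute_dp matches the plane-fit oracle and is rotation invariant", {
  set.seed(11)
  for (i in 1:25) {
    psi <- runif(1, 0.2, 1.4)
    ax <- symmetric_axes(psi)
    R <- random_rotation()
    rotated <- ax %*% t(R)
    expect_equal(compute_dp(rotated), cos(psi), tolerance = 1e-9)
    # non-symmetric vectors against the independent oracle
    e <- matrix(rnorm(9), 3, 3)
    e <- e / sqrt(rowSums(e^2))
    expect_equal(compute_dp(e), oracle_dp(e), tolerance = 1e-10)
    expect_equal(compute_dp(e %*% t(R)), compute_dp(e), tolerance = 1e-9)
  }
  # coplanar-with-origin vectors
  expect_equal(compute_dp(symmetric_axes(pi / 2)), 0, tolerance = 1e-12)
  # near-colinear limit approaches 1
  expect_equal(compute_dp(symmetric_axes(0.001)), 1, tolerance = 1e-5)
  # colinear tips are degenerate
  expect_error(compute_dp(rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))),
               "degenerate")
  expect_equal(dp_symmetric_limit(0.001), cos(0.001))
})

test_that("bending angle is zero for aligned bonds and recovers a tilt", {
  tpl <- ns_template(0)
  ff <- ff_params()
  d <- 2 * tpl$patch_offset + ff$r0_m
  a <- placed_star(tpl, c(0, 0, 0))
  b <- placed_star(tpl, c(d, 0, 0),
                   nanostargel:::quat_from_axis_angle(c(0, 0, 1), pi))
  expect_equal(bending_angle(a, 1, b, 1), 0, tolerance = 1e-9)
  # partner arm tilted 30 degrees off the common axis
  b30 <- placed_star(tpl, c(d, 0, 0),
                     nanostargel:::quat_from_axis_angle(c(0, 0, 1),
                                                        pi + pi / 6))
  expect_equal(bending_angle(a, 1, b30, 1, check = FALSE), 30,
               tolerance = 1e-9)
  # unbonded arms are rejected
  expect_error(bending_angle(a, 2, b, 2), "not bonded")
})

test_that("fixture geometry: bonded dimer distance and the six-star ring", {
  ff <- ff_params()
  dimer <- make_fixture("dimer", ff = ff)
  cc <- sqrt(sum((dimer$centers[1, ] - dimer$centers[2, ])^2))
  expect_equal(cc, 2 * 2.5 + ff$r0_m, tolerance = 1e-12)
  ring <- make_fixture("six_ring", ff = ff)
  g <- find_contacts(ring)
  expect_identical(g$N_c, 6L)
  expect_true(all(g$degrees == 2))
  # consecutive bonded arms are aligned: all bending angles zero
  phis <- phi_distribution(list(ring))
  expect_equal(max(abs(phis$phi)), 0, tolerance = 1e-8)
})
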