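test_that("volume fraction matches the reference gel conditions", {
  expect_equal(volume_fraction(175, 40), 0.01, tolerance = 3e-3)
  expect_equal(volume_fraction(1050, 40), 0.06, tolerance = 3e-3)
  expect_equal(volume_fraction(0, 40), 0)
})

test_that("trajectories are deterministic functions of the seed", {
  ff <- ff_params()
  st <- make_fixture("gas", N = 10, box_L = 16, seed = 2)
  r1 <- bd_run(st, ff, bd_params(), n_steps = 4000, record_every = 500,
               seed = 42)
  r2 <- bd_run(st, ff, bd_params(), n_steps = 4000, record_every = 500,
               seed = 42)
  expect_identical(r1$state$centers, r2$state$centers)
  expect_identical(r1$state$quats, r2$state$quats)
  expect_identical(r1$series, r2$series)
  r3 <- bd_run(st, ff, bd_params(), n_steps = 4000, record_every = 500,
               seed = 43)
  expect_false(identical(r1$state$centers, r3$state$centers))
})

test_that("rigid-body contract: quaternions stay unit, bead geometry intact", {
  ff <- ff_params()
  st <- interacting_state()
  run <- bd_run(st, ff, bd_params(), n_steps = 20000, record_every = 20000,
                seed = 3)
  q <- run$state$quats
  expect_lt(max(abs(sqrt(rowSums(q^2)) - 1)), 1e-9)
  # world beads reconstruct template-internal distances exactly
  fr <- nanostargel:::as_bead_frame(run$state)
  tpl <- st$template
  ref <- as.matrix(stats::dist(tpl$bead_positions))
  for (m in 1:4) {
    beads <- fr$positions[fr$mol == m, ]
    expect_lt(max(abs(as.matrix(stats::dist(beads)) - ref)), 1e-9)
  }
})

test_that("a free star diffuses with the imposed D_t and D_r", {
  ff0 <- ff_params(eps_m = 0)
  tpl <- ns_template(0)
  dyn <- bd_params(dt = 1e-3)
  st <- sim_state(tpl, matrix(c(8, 8, 8), 1), box_L = 16)
  run <- bd_run(st, ff0, dyn, n_steps = 250000, record_every = 100,
                save_frames = TRUE, seed = 7)
  m <- msd(run)
  for (tt in c(2, 10)) {
    i <- which.min(abs(m$t - tt))
    expect_equal(m$msd[i], 6 * dyn$D_t * m$t[i], tolerance = 0.15)
  }
  # orientation autocorrelation <e(0).e(t)> = exp(-2 D_r t)
  qs <- run$frames$quats
  nfr <- dim(qs)[1]
  ax <- t(vapply(seq_len(nfr),
                 function(i) nanostargel:::quat_rotate(qs[i, 1, ], c(1, 0, 0)),
                 numeric(3)))
  lag <- 10  # 1 tau_Br
  dots <- rowSums(ax[1:(nfr - lag), ] * ax[(1 + lag):nfr, ])
  expect_equal(mean(dots), exp(-2 * dyn$D_r * 1), tolerance = 0.05)
})

test_that("without attraction the gas stays uniform and unbonded", {
  ff0 <- ff_params(eps_m = 0)
  st <- make_fixture("gas", N = 24, box_L = 15, seed = 5)
  run <- bd_run(st, ff0, bd_params(dt = 2e-4), n_steps = 100000,
                record_every = 2000, save_frames = TRUE, seed = 9)
  # no attraction: patch proximities are rare chance encounters
  expect_lt(mean(run$series$n_contacts), 0.3)
  expect_lt(max(run$series$theta), 0.06)
  # pooled wrapped coordinates over well-separated frames stay uniform
  cen <- run$frames$centers
  xs <- as.vector(cen[seq(1, dim(cen)[1], by = 10), , ]) / 15
  ks <- suppressWarnings(stats::ks.test(xs, "punif"))
  expect_gt(ks$p.value, 1e-4)
})

test_that("two-star bond occupancy matches the brute-force MC oracle", {
  # a fast-exchange member of the model family (wide, shallower well), so
  # the occupancy statistics converge within a short run; the integrator
  # and Hamiltonian under test are the same as the study force field
  ff <- ff_params(eps_m = 14.25, a_m = 10, r0_m = 0.35)
  tpl <- ns_template(0)
  Temp <- 1.2
  L <- 15
  # oracle: importance-sampled Boltzmann weight of the bonded region
  rng <- nanostargel:::local_rng(31)
  M <- 40000
  typec <- nanostargel:::template_type_codes(tpl)
  ffc <- nanostargel:::ff_to_cpp(ff)
  beadsA <- sweep(tpl$bead_positions, 2, c(30, 30, 30), "+")
  rs <- ff$r_cut_patch
  qs <- nanostargel:::random_quats(M)
  d <- matrix(stats::runif(3 * M * 3, -rs, rs), ncol = 3)
  d <- d[rowSums(d^2) < rs^2, , drop = FALSE][seq_len(M), ]
  mol <- rep(1:2, each = 10)
  types <- c(typec, typec)
  w <- vapply(seq_len(M), function(k) {
    R <- nanostargel:::quat_to_matrix(qs[k, ])
    lb <- tpl$bead_positions %*% t(R)
    ctrB <- beadsA[8, ] + d[k, ] - lb[8, ]
    e <- nanostargel:::cpp_bead_forces(rbind(beadsA, sweep(lb, 2, ctrB, "+")),
                                       mol, types, 60, ffc)$energy
    exp(-e / Temp)
  }, numeric(1))
  rng$restore()
  K <- 9 * (4 / 3 * pi * rs^3) * mean(w) / L^3
  p_oracle <- K / (1 + K)
  # dynamics of the same Hamiltonian
  st <- sim_state(tpl, rbind(c(4, 7, 7), c(10, 7, 7)), box_L = L,
                  temperature = Temp)
  run <- bd_run(st, ff, bd_params(dt = 2e-4), n_steps = 10000000,
                record_every = 500, seed = 6)
  nc <- run$series$n_contacts
  p_bd <- mean(nc[-seq_len(2000)] > 0)
  expect_gt(p_oracle, 0.1)
  expect_lt(abs(p_bd - p_oracle), 0.12)  # both are sampled estimates
})

test_that("bonds persist at low temperature and break at high temperature", {
  ff <- ff_params()
  dimer <- make_fixture("dimer", box_L = 16, ff = ff)
  dimer$temperature <- 0.8
  cold <- bd_run(dimer, ff, bd_params(dt = 2e-4), n_steps = 250000,
                 record_every = 2500, seed = 12)
  expect_true(all(cold$series$n_contacts == 1))
  dimer$temperature <- 1.3
  hot <- bd_run(dimer, ff, bd_params(dt = 2e-4), n_steps = 1500000,
                record_every = 2500, seed = 12)
  expect_true(any(hot$series$n_contacts == 0))
})

test_that("observer callbacks see every recorded frame", {
  ff <- ff_params()
  st <- make_fixture("gas", N = 8, box_L = 16, seed = 4)
  run <- bd_run(st, ff, bd_params(), n_steps = 2000, record_every = 500,
                observers = list(nc = function(s) find_contacts(s)$N_c,
                                 t = function(s) s$time),
                seed = 5)
  expect_length(run$observed$nc, nrow(run$series))
  expect_identical(unlist(run$observed$nc), run$series$n_contacts)
  expect_equal(unlist(run$observed$t), run$series$time)
})

test_that("undersized boxes and missing seeds are rejected", {
  st <- make_fixture("gas", N = 4, box_L = 14, seed = 1)
  expect_error(bd_run(st, ff_params(), bd_params(), n_steps = 10, seed = 1),
               "too small")
  big <- make_fixture("gas", N = 4, box_L = 20, seed = 1)
  expect_error(bd_run(big, ff_params(), bd_params(), n_steps = 10),
               "seed")
})
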