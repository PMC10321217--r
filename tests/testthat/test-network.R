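test_that("theta formula with clipping", {
  expect_equal(theta_fraction(0, 10), 0)
  expect_equal(theta_fraction(1, 2), 1 / 3)
  expect_equal(theta_fraction(6, 6), 2 / 3)
  expect_equal(theta_fraction(100, 6), 1)   # clipped
})

test_that("contact detection matches an independent O(N^2) scan with greedy tie-break", {
  # R-side oracle: same greedy nearest-first semantics, written independently
  oracle_contacts <- function(st, r_bond) {
    fr <- nanostargel:::as_bead_frame(st)
    p <- fr$positions[fr$type_code == 2L, , drop = FALSE]
    mol <- fr$mol[fr$type_code == 2L]
    L <- fr$box_L
    cand <- NULL
    for (i in seq_len(nrow(p) - 1)) {
      for (j in (i + 1):nrow(p)) {
        if (mol[i] == mol[j]) next
        d <- p[i, ] - p[j, ]
        d <- d - L * round(d / L)
        dd <- sqrt(sum(d^2))
        if (dd < r_bond) cand <- rbind(cand, c(dd, i, j))
      }
    }
    if (is.null(cand)) return(0L)
    cand <- cand[order(cand[, 1]), , drop = FALSE]
    used <- logical(nrow(p)); nc <- 0L
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 2]; j <- cand[r, 3]
      if (!used[i] && !used[j]) { used[i] <- used[j] <- TRUE; nc <- nc + 1L }
    }
    nc
  }
  ff <- ff_params()
  for (st in list(make_fixture("dimer", ff = ff),
                  make_fixture("six_ring", ff = ff),
                  make_fixture("gas", N = 20, box_L = 16, seed = 4),
                  interacting_state())) {
    for (rb in c(0.3, 0.55, 1.2)) {
      expect_identical(find_contacts(st, rb)$N_c, oracle_contacts(st, rb))
    }
  }
  # a gas built with rejection carries no contacts
  gas <- make_fixture("gas", N = 30, box_L = 20, seed = 10, ff = ff)
  expect_identical(find_contacts(gas)$N_c, 0L)
})

test_that("single-bond-per-patch: the nearest of several in-range partners wins", {
  tpl <- ns_template(0)
  rot <- function(a) nanostargel:::quat_from_axis_angle(c(0, 0, 1), a)
  # A's arm-1 patch sits at (22.5, 20, 20). B's patch is 0.25 away along x,
  # C's patch 0.52 away along y; B and C patches are 0.577 apart (out of
  # range), so greedy matching must bond A-B only.
  st <- sim_state(tpl,
                  rbind(c(20, 20, 20), c(25.25, 20, 20),
                        c(22.5, 23.02, 20)),
                  rbind(c(1, 0, 0, 0), rot(pi), rot(-pi / 2)),
                  box_L = 40)
  g <- find_contacts(st, 0.55)
  expect_identical(g$N_c, 1L)
  expect_identical(sort(c(g$bonds$mol_a, g$bonds$mol_b)), c(1L, 2L))
  expect_true(all(g$degrees <= tpl$f))
})

test_that("graph metrics: degrees, components, largest-component fraction", {
  ring <- make_fixture("six_ring")
  gm <- graph_metrics(find_contacts(ring))
  expect_equal(unname(gm$degree_hist), c(0, 0, 6, 0))
  expect_equal(gm$c_s, 1)
  # two disjoint dimers: c_s = 0.5
  tpl <- ns_template(0)
  ff <- ff_params()
  d <- 5 + ff$r0_m
  rot <- nanostargel:::quat_from_axis_angle(c(0, 0, 1), pi)
  st <- sim_state(tpl,
                  rbind(c(5, 5, 5), c(5 + d, 5, 5),
                        c(5, 25, 25), c(5 + d, 25, 25)),
                  rbind(c(1, 0, 0, 0), rot, c(1, 0, 0, 0), rot),
                  box_L = 40)
  gm2 <- graph_metrics(find_contacts(st))
  expect_equal(gm2$c_s, 0.5)
  expect_equal(gm2$n_components, 2)
  expect_equal(unname(gm2$degree_hist), c(0, 4, 0, 0))
})

test_that("melting curve interpolation and bracketing errors", {
  tab <- data.frame(temperature = c(0.9, 1.1, 1.3), theta = c(1, 0.5, 0))
  expect_equal(melting_curve(tab)$T_m, 1.1)
  tab2 <- data.frame(temperature = c(0.9, 1.0, 1.2), theta = c(0.9, 0.7, 0.3))
  expect_equal(melting_curve(tab2)$T_m, 1.1)   # linear interpolation
  expect_error(melting_curve(data.frame(temperature = c(1, 2),
                                        theta = c(0.9, 0.8))),
               "no theta = 0.5 crossing")
})

test_that("relaxation time recovers an AR(1) decay constant within 10%", {
  tau <- 50; dt <- 1
  phi <- exp(-dt / tau)
  set.seed(123)
  n <- 150000
  x <- stats::arima.sim(list(ar = phi), n)
  est <- relaxation_time(as.numeric(x), dt)
  expect_false(est$flagged)
  expect_equal(est$tau_c, tau, tolerance = 0.10)
  # white noise decorrelates within one sampling interval
  wn <- relaxation_time(rnorm(5000), dt)
  expect_lt(wn$tau_c, 2 * dt)
  # a frozen (constant) series is flagged as non-decaying
  frozen <- relaxation_time(rep(5, 100), dt)
  expect_true(frozen$flagged)
})

test_that("Arrhenius fit is exact on noiseless data, unbiased on noisy data", {
  temps <- c(0.9, 1.0, 1.1, 1.2, 1.3)
  tau <- 0.8 * exp(9.7 / temps)
  fit <- suppressWarnings(arrhenius_fit(temps, tau))
  expect_equal(fit$a, 0.8, tolerance = 1e-10)
  expect_equal(fit$E_a, 9.7, tolerance = 1e-10)
  set.seed(5)
  ok <- 0
  for (rep in 1:10) {
    noisy <- tau * exp(rnorm(5, sd = 0.1))
    f2 <- arrhenius_fit(temps, noisy)
    se <- sqrt(diag(f2$covariance))[2]
    if (abs(f2$E_a - 9.7) < 2 * se) ok <- ok + 1
  }
  expect_gte(ok, 8)
  expect_error(arrhenius_fit(c(1, 1.1), c(10, 5)), "at least 3")
})

test_that("MSD: ballistic closed form and wrapped-input detection", {
  nf <- 60; nstar <- 3
  v <- c(0.3, -0.2, 0.1)
  times <- seq(0, by = 0.5, length.out = nf)
  cen <- array(0, c(nf, nstar, 3))
  for (k in 1:3) cen[, , k] <- outer(times * v[k], rep(1, nstar))
  m <- msd(cen, times = times)
  expect_equal(m$msd, sum(v^2) * m$t^2, tolerance = 1e-10)
  # wrapped trajectories (jumps > L/2) are refused
  wrapped <- cen
  wrapped[30, , 1] <- wrapped[30, , 1] + 12
  expect_error(msd(wrapped, times = times, box_L = 10), "wrapped")
})

test_that("g(r) is flat for an ideal gas and integrates to the coordination", {
  set.seed(9)
  L <- 20
  frames <- lapply(1:25, function(i) matrix(runif(3 * 300, 0, L), ncol = 3))
  g <- rdf(frames, box_L = L, bin_w = 0.25)
  expect_lt(mean(abs(g$g[g$r > 1] - 1)), 0.05)
  expect_error(rdf(frames, box_L = L, r_max = 11), "half the box")
  # two fixed cores 5.12 sigma apart occupy a single bin
  two <- matrix(c(5, 5, 5, 10.12, 5, 5), 2, 3, byrow = TRUE)
  g2 <- rdf(two, box_L = 40, bin_w = 0.1, r_max = 10)
  expect_identical(which(g2$g > 0), which(g2$r > 5.1 & g2$r < 5.2))
  # six-ring: first-shell integral 4 pi rho int g r^2 dr = mean degree 2
  ring <- make_fixture("six_ring")
  cores <- nanostargel:::as_bead_frame(ring)
  cp <- cores$positions[cores$type_code == 0L, ]
  gr <- rdf(cp, box_L = 40, bin_w = 0.1, r_max = 12)
  rho <- 5 / 40^3   # (N - 1)/V: pair-count convention at small N
  shell <- gr$r > 4.8 & gr$r < 6
  coord <- sum(4 * pi * rho * gr$g[shell] * gr$r[shell]^2 * 0.1)
  expect_equal(coord, 2, tolerance = 0.05)
})

test_that("bending-angle histogram is a delta at zero for the aligned ring", {
  ring <- make_fixture("six_ring")
  ph <- phi_distribution(list(ring))
  expect_equal(length(ph$phi), 6)
  expect_lt(max(ph$phi), 1e-8)
  expect_equal(ph$mode, 2.5)  # centre of the first 5-degree bin
})
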