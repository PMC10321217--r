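test_that("Gaussian deposition: single evaluation, linearity, clamping", {
  b <- bias_potential(w = 1, delta = 0.1, bounds = c(0, 1))
  b <- meta_deposit(b, 0.5)
  expect_equal(bias_energy(b, 0.5), 1)
  expect_equal(bias_energy(b, 0.8), exp(-4.5), tolerance = 1e-12)
  b2 <- meta_deposit(b, 0.5)
  expect_equal(bias_energy(b2, c(0.3, 0.5, 0.9)),
               2 * bias_energy(b, c(0.3, 0.5, 0.9)))
  expect_warning(meta_deposit(b, 1.4), "clamped")
})

test_that("well-tempered heights decay by the closed-form recursion", {
  dT <- 2
  b <- bias_potential(w = 0.5, delta = 0.1, well_tempered = dT,
                      bounds = c(-1, 1))
  for (i in 1:6) b <- meta_deposit(b, 0)
  # independent recursion: w_{n+1} = w exp(-sum_{k<=n} w_k / dT)
  h <- numeric(6)
  for (i in 1:6) h[i] <- 0.5 * exp(-sum(h[seq_len(i - 1)]) / dT)
  expect_equal(b$heights, h, tolerance = 1e-12)
  expect_true(all(b$heights > 0))
  # the accumulated bias never decreases anywhere as deposits accumulate
  grid <- seq(-1, 1, length.out = 101)
  expect_true(all(bias_energy(meta_deposit(b, 0.3), grid) >=
                  bias_energy(b, grid) - 1e-12))
})

test_that("bias force follows the chain rule through the CV gradient", {
  b <- bias_potential(w = 0.7, delta = 0.2, bounds = c(-2, 2))
  grad <- c(0.3, -1, 2)
  expect_equal(bias_force(b, 0.1, grad), c(0, 0, 0))     # empty bias
  b <- meta_deposit(b, 0)
  expect_equal(bias_force(b, 0, grad), c(0, 0, 0))       # at the centre
  # one width off-centre: |dU/dz| = (w / delta) exp(-1/2)
  f <- bias_force(b, 0.2, grad)
  expect_equal(f, -(-0.7 / 0.2 * exp(-0.5)) * grad, tolerance = 1e-12)
})

test_that("free-energy estimate recovers a known harmonic landscape", {
  k_true <- 6
  bias <- bias_potential(w = 0.12, delta = 0.1, stride = 300,
                         well_tempered = 8, temperature = 1,
                         bounds = c(-1.6, 1.6))
  run <- run_metadynamics_1d(function(x) k_true * x, bias, x0 = 0,
                             n_steps = 250000, dt = 2e-3, seed = 21)
  fel <- run$fel
  sel <- abs(fel$zeta) < 0.9
  fit <- stats::lm(fel$F[sel] ~ I(fel$zeta[sel]^2))
  expect_equal(2 * unname(stats::coef(fit)[2]), k_true, tolerance = 0.15)
  # a flat landscape stays flat within the deposition noise floor
  flat <- run_metadynamics_1d(function(x) 0 * x,
                              bias_potential(w = 0.05, delta = 0.15,
                                             stride = 200,
                                             well_tempered = 8,
                                             bounds = c(-1, 1)),
                              x0 = 0, n_steps = 150000, dt = 2e-3, seed = 4)
  inner <- abs(flat$fel$zeta) < 0.8
  expect_lt(diff(range(flat$fel$F[inner])), 1.0)
})

test_that("planarity CV matches the geometry oracle with a consistent gradient", {
  # symmetric molecule: d_p = cos(psi)
  tips <- symmetric_axes(acos(0.6)) * 1.3   # non-unit arms
  cv <- dp_cv(c(0, 0, 0), tips)
  expect_equal(cv$value, 0.6, tolerance = 1e-12)
  set.seed(77)
  for (i in 1:10) {
    core <- rnorm(3, sd = 0.3)
    tips <- matrix(rnorm(9, sd = 1), 3, 3) + rep(1, 3) %o% core
    val <- try(dp_cv(core, tips), silent = TRUE)
    if (inherits(val, "try-error")) next
    # value agrees with compute_dp on the normalized core->tip vectors
    e <- sweep(tips, 2, core, "-")
    expect_equal(val$value, compute_dp(e), tolerance = 1e-10)
    # analytic gradient vs central differences
    h <- 1e-6
    num <- matrix(0, 4, 3)
    coords <- rbind(core, tips)
    for (b in 1:4) for (k in 1:3) {
      cp <- coords; cp[b, k] <- cp[b, k] + h
      cm <- coords; cm[b, k] <- cm[b, k] - h
      num[b, k] <- (dp_cv(cp[1, ], cp[2:4, ])$value -
                    dp_cv(cm[1, ], cm[2:4, ])$value) / (2 * h)
    }
    expect_lt(max(abs(num - val$gradient)), 1e-6)
    # invariance under rigid motion
    R <- random_rotation()
    shift <- rnorm(3)
    moved <- sweep(coords %*% t(R), 2, shift, "+")
    expect_equal(dp_cv(moved[1, ], moved[2:4, ])$value, val$value,
                 tolerance = 1e-9)
  }
})

test_that("biasing the planarity CV drives a flexible Y out of plane", {
  unbiased <- flexible_y_demo(n_steps = 30000, seed = 2)
  bias <- bias_potential(w = 0.15, delta = 0.05, stride = 100,
                         bounds = c(0, 1))
  biased <- flexible_y_demo(n_steps = 40000, bias = bias, seed = 2)
  expect_lt(stats::quantile(unbiased$d_p, 0.99), 0.5)
  expect_gt(max(biased$d_p), 0.6)
})
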