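test_that("series solution satisfies the boundary and initial conditions", {
  for (tt in c(0.01, 0.1, 1, 5)) expect_equal(phi_series(tt, 0), 1)
  p0 <- dimensionless_profile(0, 11)
  expect_equal(p0$phi, c(1, rep(0, 10)))
  # no-flux wall: one-sided difference at eta = 1 is tiny for tau >= 0.05
  h <- 1e-4
  for (tt in c(0.05, 0.3, 1.5)) {
    expect_lt(abs(phi_series(tt, 1) - phi_series(tt, 1 - h)) / h, 1e-3)
  }
})

test_that("series evaluation matches frozen brute-force values", {
  expect_equal(phi_series(0.1, 1), 0.0506946373, tolerance = 1e-8)
  expect_equal(phi_series(1.5, 1), 0.9685556881, tolerance = 1e-8)
  expect_equal(phi(0.005, 0.2), 0.0455002639, tolerance = 1e-6)
  # and the independent fixed-term sum across a tau/eta grid
  for (tt in c(0.02, 0.1, 0.5, 2)) {
    eta <- seq(0, 1, 0.05)
    expect_equal(phi_series(tt, eta), brute_phi(tt, eta), tolerance = 1e-10)
  }
})

test_that("small-time similarity form matches erfc and the series", {
  expect_equal(phi_smalltau(0.005, 0), 1)
  expect_equal(phi_smalltau(0.005, 0.1), ref_erfc(0.1 / (2 * sqrt(0.005))),
               tolerance = 1e-12)
  expect_lt(phi_smalltau(0.005, 1), 1e-10) # far wall effectively unreached
  # hand-over between the two evaluations at the switch time
  eta <- seq(0, 1, 0.01)
  expect_lt(max(abs(phi_series(0.01, eta) - phi_smalltau(0.01, eta))), 1e-6)
})

test_that("phi is monotone in position and time, and tends to 1", {
  eta <- seq(0, 1, 0.05)
  for (tt in c(0.005, 0.1, 0.3, 0.8, 1.5)) {
    expect_true(all(diff(phi(tt, eta)) <= 1e-12))
  }
  taus <- c(0.01, 0.05, 0.2, 0.5, 1, 2, 4)
  for (e in c(0.2, 0.5, 1)) {
    expect_true(all(diff(vapply(taus, phi, 1, eta = e)) >= -1e-12))
  }
  expect_true(all(phi_series(30, eta) > 1 - 1e-6))
})

test_that("profiles are clamped to [0,1] and validated", {
  p <- dimensionless_profile(0.1, 11)
  expect_true(all(p$phi >= 0 & p$phi <= 1))
  expect_equal(p$phi[11], 0.0507, tolerance = 1e-3)
  expect_error(dimensionless_profile(0.1, 1), class = "papm_invalid_parameter")
  expect_error(phi_series(0, 0.5), class = "papm_invalid_parameter")
  expect_error(phi_series(0.1, 0.5, tol = 0), class = "papm_invalid_parameter")
  expect_error(phi_series(0.1, 1.5), class = "papm_invalid_parameter")
})

test_that("tau/time mapping reproduces the reference time list", {
  t_s <- tau_to_time(c(0.005, 0.1, 0.3, 0.8, 1.5))
  expect_equal(signif(t_s, 3), c(1.67e-5, 3.33e-4, 1e-3, 2.67e-3, 5e-3))
  expect_equal(tau_to_time(1.5, 1000, 10), 0.150)
  set.seed(3)
  x <- 10^runif(10, -6, 0)
  expect_equal(time_to_tau(tau_to_time(x)), x, tolerance = 1e-12)
  expect_error(tau_to_time(-1), class = "papm_invalid_parameter")
})

test_that("steady-state time matches the leading-term closed form", {
  tau05 <- steady_state_tau(0.05)
  expect_equal(tau05, 4 / pi^2 * log(4 / (pi * 0.05)), tolerance = 1e-2)
  expect_gt(tau05, 1.25)
  expect_lt(tau05, 1.4) # tau = 1.5 comfortably satisfies it
  expect_lt(1 - phi_series(1.5, 1), 0.05)
  # monotone decreasing in epsilon, shrinking towards 0 as epsilon -> 1
  # (the wall deficit decays like erfc(1/(2 sqrt(tau))), so the shrinkage
  # is logarithmically slow)
  eps <- c(0.01, 0.05, 0.2, 0.6, 0.99)
  tt <- vapply(eps, steady_state_tau, 1)
  expect_true(all(diff(tt) < 0))
  expect_lt(tt[length(tt)], 0.1)
  expect_error(steady_state_tau(1.2), class = "papm_invalid_parameter")
})
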