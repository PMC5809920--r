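test_that("both finite-difference schemes agree with the analytic series", {
  for (tt in c(0.005, 0.1, 0.3, 0.8, 1.5)) {
    dti <- if (tt <= 0.01) 1e-6 else 1e-4
    fi <- solve_fd(tt, fd_grid(120, dti, "implicit"))
    fe <- solve_fd(tt, fd_grid(120, 1e-5, "explicit"))
    ref <- phi(tt, fi$eta)
    expect_lt(max(abs(fi$phi - ref)), 1e-3)
    expect_lt(max(abs(fe$phi - ref)), 1e-3)
    expect_lt(attr(fi, "flux_residual"), 1e-8)
  }
})

test_that("trivial limits: initial condition and steady state", {
  g <- fd_grid(60, 1e-3)
  f0 <- solve_fd(0, g)
  expect_equal(f0$phi, c(1, rep(0, 61)))
  fs <- solve_fd(10, g)
  expect_true(all(abs(fs$phi - 1) < 1e-3))
})

test_that("explicit scheme rejects unstable step sizes", {
  expect_error(fd_grid(50, 0.01, "explicit"), "0.5",
               class = "papm_invalid_parameter")
  expect_error(fd_grid(5, 1e-4), class = "papm_invalid_parameter")
})

test_that("spatial refinement reduces the error at the scheme's order", {
  err <- function(n) {
    f <- solve_fd(0.3, fd_grid(n, 1e-5, "implicit"))
    max(abs(f$phi - phi_series(0.3, f$eta)))
  }
  e_coarse <- err(40)
  e_fine <- err(120)
  expect_gt(e_coarse / e_fine, 3) # second order in space: expect ~9x
})

test_that("particle walk is reproducible given its seed", {
  a <- particle_walk(0.1, 500, seed = 99, n_sites = 11)
  b <- particle_walk(0.1, 500, seed = 99, n_sites = 11)
  c <- particle_walk(0.1, 500, seed = 100, n_sites = 11)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, c$counts))
})

test_that("particle walk reproduces the continuum profile at large numbers", {
  w <- particle_walk(0.3, n_source = 20000, seed = 7, n_sites = 21, n_reps = 6)
  ref <- phi(w$tau, w$eta) * w$n_source
  tol <- pmax(3 * w$se, 3 * sqrt(pmax(ref, 1))) # 3 MC standard errors
  expect_true(all(abs(w$counts - ref) <= tol))
})

test_that("low-copy dispersion is visible at the earliest time point", {
  # at the ~8-molecule scale of the earliest time the near-source occupancy
  # fluctuates strongly between realizations: the continuum reading is an
  # expectation, not a per-realization count
  w <- particle_walk(0.005, n_source = 6, seed = 21, n_sites = 21, n_reps = 30)
  expect_true(any(w$se > 0))
  expect_gt(max(w$se) * sqrt(30), 0.5) # per-replicate sd of order one molecule
})
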