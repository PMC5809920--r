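test_that("allocation reproduces the published face counts", {
  # 100 PLC at 5000/s after 333 us (tau = 0.1): 41 near the source, 2 at the store
  mp1 <- allocate_molecules(dimensionless_profile(0.1), 500000 / 3000)
  expect_equal(near_alpha(mp1), 41)
  expect_equal(near_beta(mp1), 2)
  # after 1 ms (tau = 0.3) with 500 molecules: 29 at the store face
  expect_equal(near_beta(allocate_molecules(dimensionless_profile(0.3), 500)), 29)
  # after 2.67 ms (tau = 0.8) with 1335: 112
  expect_equal(near_beta(allocate_molecules(dimensionless_profile(0.8), 1335)), 112)
  # near steady state (tau = 1.5) with 2500: 225
  expect_equal(near_beta(allocate_molecules(dimensionless_profile(1.5), 2500)), 225)
  # nothing synthesized, nothing anywhere
  mp0 <- allocate_molecules(dimensionless_profile(0.3), 0)
  expect_true(all(mp0$counts == 0))
  expect_false(mp0$degenerate)
})

test_that("visibility rule keeps only positions with >= 1 expected molecule", {
  # 16.7 us with 100 PLC at 5000/s: ~8.35 molecules, front ~100 nm deep
  mp <- allocate_molecules(dimensionless_profile(0.005), 8.35)
  vis <- visible_profile(mp)
  expect_equal(vis$z_nm, c(0, 100))
  expect_equal(vis$counts, c(6, 2))
  expect_false(vis$degenerate)
})

test_that("sub-single-molecule expectations everywhere are flagged degenerate", {
  # 1 PLC at 1000/s after 5 ms synthesizes 5 molecules; on the tau = 1.5
  # profile every grid expectation is below one molecule
  mp <- allocate_molecules(dimensionless_profile(1.5), 5)
  expect_true(mp$degenerate)
  expect_true(all(mp$expected < 1))
  vis <- visible_profile(mp)
  expect_length(vis$counts, 0)
  expect_true(vis$degenerate)
})

test_that("rounding conserves mass within half a molecule per grid point", {
  set.seed(17)
  for (i in 1:30) {
    tau <- runif(1, 0.02, 2)
    n <- runif(1, 1, 3000)
    np <- sample(5:31, 1)
    mp <- allocate_molecules(dimensionless_profile(tau, np), n)
    expect_lte(abs(sum(mp$counts) - mp$total), np / 2)
    expect_true(all(mp$counts >= 0))
    expect_true(all(diff(mp$counts) <= 0)) # inherits phi's monotonicity
    lr <- allocate_molecules(dimensionless_profile(tau, np), n,
                             method = "largest_remainder")
    expect_identical(sum(lr$counts), lr$total)
  }
})

test_that("allocation is scale-equivariant within rounding", {
  p <- dimensionless_profile(0.3)
  for (n in c(50, 167, 500)) {
    c1 <- allocate_molecules(p, n)$counts
    c2 <- allocate_molecules(p, 2 * n)$counts
    expect_true(all(abs(c2 - 2 * c1) <= 2))
  }
})

test_that("an identically zero profile cannot absorb a positive total", {
  z <- papm:::new_profile(0.1, seq(0, 1, 0.1), rep(0, 11))
  expect_error(allocate_molecules(z, 10), class = "papm_degenerate_profile")
  expect_silent(allocate_molecules(z, 0))
})

test_that("the end-to-end molecule table matches the golden reference", {
  tbl <- ip3_table()
  expect_true(isTRUE(check_table3(tbl)))
  ref <- table3_reference()
  expect_equal(tbl$total_ip3, ref$total_ip3)
  expect_equal(tbl$near_beta, ref$near_beta)
})

test_that("single-row and empty scenario tables work", {
  one <- ip3_table(data.frame(n_plc = 10, kcat_per_s = 1000, time_s = 5e-3,
                              tau = 1.5))
  expect_equal(one$total_ip3, 50)
  expect_equal(one$near_beta, 4)
  empty <- ip3_table(table3_scenarios()[0, ])
  expect_equal(nrow(empty), 0)
})
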