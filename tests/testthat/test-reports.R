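test_that("run_profile accepts exactly one of tau and time_s", {
  p1 <- run_profile(tau = 1.5)
  p2 <- run_profile(time_s = 5e-3)
  expect_equal(p1$phi, p2$phi)
  expect_equal(p2$tau[1], 1.5)
  expect_equal(p1$time_s[1], 5e-3)
  expect_equal(nrow(p1), 11)
  expect_equal(run_profile(tau = 0.1)$phi[11], 0.0507, tolerance = 1e-3)
  expect_equal(run_profile(tau = 0, config = papm_config(n_points = 5))$phi,
               c(1, 0, 0, 0, 0))
  expect_error(run_profile(), class = "papm_invalid_parameter")
  expect_error(run_profile(tau = 0.1, time_s = 1e-3),
               class = "papm_invalid_parameter")
})

test_that("YAML configs load, override defaults, and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "dab_um2_s: 10",
    "n_points: 5",
    "scenarios:",
    "  - n_plc: 100",
    "    kcat_per_s: 5000",
    "    time_s: 0.15",
    "    tau: 1.5"
  ), path)
  cfg <- load_config(path)
  expect_equal(cfg$constants$dab_um2_s, 10)
  expect_equal(cfg$n_points, 5)
  expect_equal(cfg$scenarios$time_s, 0.15)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("dab_umm2_s: 10", bad)
  expect_error(load_config(bad), "dab_umm2_s",
               class = "papm_invalid_parameter")
  expect_error(load_config("no/such/file.yaml"),
               class = "papm_invalid_parameter")
})

test_that("run_table3 check mode flags golden mismatches", {
  expect_silent(tbl <- run_table3(check = TRUE))
  expect_equal(nrow(tbl), 14)
  cfg <- papm_config(constants = papm_constants(degradation_horizon_s = 5),
                     pip2_budget = 100) # starves synthesis: totals change
  expect_error(run_table3(cfg, check = TRUE), class = "papm_golden_mismatch")
})

test_that("diffusivity sweep exposes the 30-fold slowdown at Dab = 10", {
  sw <- run_sweep(100, 5000, tau = 1.5, dab_um2_s = c(10, 300))
  expect_equal(sort(sw$time_s), c(5e-3, 0.150))
  expect_equal(max(sw$time_s) / min(sw$time_s), 30)
  # a single-point sweep reduces to the corresponding table row
  one <- run_sweep(100, 5000, tau = 1.5, dab_um2_s = 300)
  expect_equal(one$total_ip3, 2500)
  expect_equal(one$near_beta, 225)
  expect_error(run_sweep(numeric(0), 5000), class = "papm_invalid_parameter")
})

test_that("profile CSV round-trips into identical allocations", {
  df <- run_profile(tau = 0.3)
  path <- withr::local_tempfile(fileext = ".csv")
  export_results(df, csv = path)
  back <- utils::read.csv(path)
  p1 <- papm:::new_profile(df$tau[1], df$eta, df$phi)
  p2 <- papm:::new_profile(back$tau[1], back$eta, back$phi)
  expect_identical(allocate_molecules(p1, 500)$counts,
                   allocate_molecules(p2, 500)$counts)
})
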