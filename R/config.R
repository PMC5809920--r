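#' Run configuration for the end-to-end analysis
#'
#' Bundles geometry, physical constants, the scenario grid and the
#' allocation grid size. All defaults are the model's reference values, so
#' `papm_config()` with no arguments reproduces the published analysis.
#'
#' @param geometry A [papm_geometry()].
#' @param constants A [papm_constants()].
#' @param scenarios Scenario data frame (see [table3_scenarios()]).
#' @param n_points Allocation grid size.
#' @param pip2_budget PIP2 budget, molecules.
#' @param seed RNG seed used by stochastic validators.
#' @return An object of class `papm_config`.
#' @export
papm_config <- function(geometry = papm_geometry(),
                        constants = papm_constants(),
                        scenarios = table3_scenarios(),
                        n_points = 11L, pip2_budget = 3000, seed = 1L) {
  stopifnot(inherits(geometry, "papm_geometry"),
            inherits(constants, "papm_constants"),
            is.data.frame(scenarios))
  check_nonnegative(pip2_budget, "pip2_budget")
  structure(
    list(geometry = geometry, constants = constants, scenarios = scenarios,
         n_points = n_points, pip2_budget = pip2_budget,
         seed = as.integer(seed)),
    class = "papm_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Recognized top-level keys: `length_nm`, `diameter_nm`, `dab_um2_s`,
#' `degradation_horizon_s`, `pip2_budget`, `n_points`, `seed`, and
#' `scenarios` (a list of mappings with `n_plc`, `kcat_per_s`, `time_s` and
#' optional `tau`). Any other key is rejected with a message naming it, so a
#' typo cannot silently fall back to a default.
#'
#' @param path Path to a YAML file.
#' @return A [papm_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- c("length_nm", "diameter_nm", "dab_um2_s",
               "degradation_horizon_s", "pip2_budget", "n_points", "seed",
               "scenarios")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "),
                 " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  pick <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  scenarios <- if (is.null(raw$scenarios)) {
    table3_scenarios()
  } else {
    rows <- lapply(raw$scenarios, function(s) {
      need <- c("n_plc", "kcat_per_s", "time_s")
      miss <- setdiff(need, names(s))
      if (length(miss)) {
        stop_invalid("scenario entry missing key(s): ",
                     paste(miss, collapse = ", "))
      }
      data.frame(n_plc = s$n_plc, kcat_per_s = s$kcat_per_s,
                 time_s = s$time_s,
                 tau = if (is.null(s$tau)) NA_real_ else s$tau)
    })
    df <- do.call(rbind, rows)
    if (all(is.na(df$tau))) df$tau <- NULL
    df
  }
  papm_config(
    geometry = papm_geometry(pick("length_nm", 1000), pick("diameter_nm", 100)),
    constants = papm_constants(pick("dab_um2_s", 300),
                               pick("degradation_horizon_s", 0.8)),
    scenarios = scenarios,
    n_points = pick("n_points", 11L),
    pip2_budget = pick("pip2_budget", 3000),
    seed = pick("seed", 1L)
  )
}

#' Compute a concentration profile from a tau or a physical time
#'
#' Exactly one of `tau` and `time_s` must be given; the other is derived
#' through `t = tau * L^2 / Dab` using the configuration's geometry and
#' diffusivity.
#'
#' @param tau Dimensionless time (>= 0).
#' @param time_s Physical time in seconds (> 0).
#' @param config A [papm_config()].
#' @return A data frame with columns `tau`, `time_s`, `eta`, `z_nm`, `phi`.
#' @export
#' @examples
#' run_profile(tau = 0.1)
#' run_profile(time_s = 5e-3) # same as tau = 1.5 at the defaults
run_profile <- function(tau = NULL, time_s = NULL, config = papm_config()) {
  if (is.null(tau) == is.null(time_s)) {
    stop_invalid("give exactly one of tau and time_s")
  }
  L <- config$geometry$length_nm
  dab <- config$constants$dab_um2_s
  if (is.null(tau)) {
    tau <- time_to_tau(time_s, L, dab)
  } else if (tau > 0) {
    time_s <- tau_to_time(tau, L, dab)
  } else {
    time_s <- 0
  }
  p <- dimensionless_profile(tau, config$n_points)
  data.frame(tau = tau, time_s = time_s, eta = p$eta, z_nm = p$eta * L,
             phi = p$phi)
}

#' Run the scenario grid end to end
#'
#' @param config A [papm_config()].
#' @param check If `TRUE` and the configuration uses the default scenario
#'   grid, stop with an error unless the result matches the golden
#'   reference ([table3_reference()]).
#' @return The [ip3_table()] data frame.
#' @export
run_table3 <- function(config = papm_config(), check = FALSE) {
  tbl <- ip3_table(config$scenarios, config$geometry, config$constants,
                   config$n_points, config$pip2_budget)
  if (check) {
    ok <- check_table3(tbl)
    if (!isTRUE(ok)) {
      stop(errorCondition(
        "molecule table does not match the golden reference",
        class = "papm_golden_mismatch"
      ))
    }
  }
  tbl
}

#' Cartesian parameter sweep over PLC conditions, times and diffusivities
#'
#' Expands `n_plc x kcat_per_s x tau x dab_um2_s`, computing for every
#' combination the physical time, the synthesized total and the near-store
#' count. Because `tau` fixes the shape of the profile, sweeping `dab_um2_s`
#' only rescales physical time (t = tau L^2 / Dab): the disputed 30-fold
#' slower diffusivity (10 vs 300 um^2/s) turns 5 ms into 150 ms but leaves
#' every molecule count unchanged.
#'
#' @param n_plc,kcat_per_s,tau,dab_um2_s Sweep axes (non-empty vectors).
#' @param config A [papm_config()] providing geometry, budget and grid size.
#' @return A long-format data frame with one row per combination.
#' @export
#' @examples
#' run_sweep(100, 5000, tau = 1.5, dab_um2_s = c(10, 300))
run_sweep <- function(n_plc = c(1, 10, 100), kcat_per_s = c(1000, 5000),
                      tau = c(0.005, 0.1, 0.3, 0.8, 1.5),
                      dab_um2_s = 300, config = papm_config()) {
  axes <- list(n_plc = n_plc, kcat_per_s = kcat_per_s, tau = tau,
               dab_um2_s = dab_um2_s)
  empty <- names(axes)[vapply(axes, length, 1L) == 0L]
  if (length(empty)) {
    stop_invalid("empty sweep axis: ", paste(empty, collapse = ", "))
  }
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  L <- config$geometry$length_nm
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    t_s <- tau_to_time(g$tau, L, g$dab_um2_s)
    scn <- synthesis_scenario(g$n_plc, g$kcat_per_s, config$pip2_budget)
    ntot <- total_ip3(scn, t_s, config$constants$degradation_horizon_s)
    mp <- allocate_molecules(dimensionless_profile(g$tau, config$n_points),
                             ntot, L, t_s)
    cbind(g, time_s = t_s, total_ip3 = mp$total, near_beta = near_beta(mp),
          degenerate = mp$degenerate)
  })
  do.call(rbind, out)
}

#' Cross-validate the analytical series against the numerical oracles
#'
#' Computes, for each `tau`, the maximal absolute discrepancy between the
#' eigenfunction series and the implicit and explicit finite-difference
#' solutions.
#'
#' @param taus Dimensionless times to check.
#' @param n_space Interior FD points.
#' @param d_tau_implicit,d_tau_explicit Time steps for the two schemes.
#' @return A data frame with columns `tau`, `linf_implicit`,
#'   `linf_explicit`, `flux_residual`.
#' @export
oracle_check <- function(taus = c(0.005, 0.1, 0.3, 0.8, 1.5),
                         n_space = 120L, d_tau_implicit = 1e-5,
                         d_tau_explicit = 1e-5) {
  out <- lapply(taus, function(tt) {
    fi <- solve_fd(tt, fd_grid(n_space, d_tau_implicit, "implicit"))
    fe <- solve_fd(tt, fd_grid(n_space, d_tau_explicit, "explicit"))
    ref <- phi(tt, fi$eta)
    data.frame(
      tau = tt,
      linf_implicit = max(abs(fi$phi - ref)),
      linf_explicit = max(abs(fe$phi - ref)),
      flux_residual = attr(fi, "flux_residual")
    )
  })
  do.call(rbind, out)
}
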