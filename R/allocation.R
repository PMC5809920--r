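#' Allocate a synthesized IP3 total onto the concentration profile
#'
#' The area under the dimensionless profile is proportional to the total
#' amount of substance that has entered the cylinder, so the expected number
#' of molecules attributed to grid point i is `n_total * phi_i / sum(phi)`.
#' Counts are the nearest integers of these expectations (see
#' [round_count()]); the real-valued expectations are kept alongside because
#' the visibility rule and the low-copy caveat are defined on them.
#'
#' When every expectation is below one molecule the continuum profile cannot
#' be read as molecule positions at all; the result is flagged `degenerate`
#' rather than silently rounded to zeros.
#'
#' @param profile A `papm_profile` from [dimensionless_profile()] (or
#'   [solve_fd()]).
#' @param n_total Real-valued total molecule count to distribute (>= 0),
#'   typically from [total_ip3()].
#' @param length_nm Projection length, used to report physical positions.
#' @param time_s Optional physical time bookkeeping field.
#' @param method `"independent"` rounds each grid point separately (the
#'   reference tables' convention; the grid sum may then differ from the
#'   rounded total by up to half the number of points). `"largest_remainder"`
#'   floors all points and hands out the remaining molecules by largest
#'   fractional part, making the grid sum exactly the rounded total.
#' @return An object of class `papm_molecule_profile` with fields `time_s`,
#'   `tau`, `eta`, `z_nm`, `expected`, `counts`, `total` and `degenerate`.
#' @export
#' @examples
#' prof <- dimensionless_profile(0.1)
#' mp <- allocate_molecules(prof, 500000 / 3000) # 100 PLC at 5000/s, 333 us
#' near_alpha(mp); near_beta(mp)
allocate_molecules <- function(profile, n_total, length_nm = 1000,
                               time_s = NA_real_,
                               method = c("independent", "largest_remainder")) {
  stopifnot(inherits(profile, "papm_profile"))
  check_nonnegative(n_total, "n_total")
  if (length(n_total) != 1L) stop_invalid("n_total must be a single value")
  method <- match.arg(method)
  sphi <- sum(profile$phi)
  if (sphi == 0 && n_total > 0) {
    stop(errorCondition(
      "profile is identically zero: cannot distribute a positive total",
      class = c("papm_degenerate_profile", "papm_invalid_parameter")
    ))
  }
  expected <- if (n_total == 0) numeric(length(profile$phi)) else n_total * profile$phi / sphi
  total <- round_count(n_total)
  counts <- switch(method,
    independent = round_count(expected),
    largest_remainder = {
      base <- floor(expected)
      rem <- total - sum(base)
      frac <- expected - base
      if (rem > 0) {
        top <- order(frac, decreasing = TRUE)[seq_len(rem)]
        base[top] <- base[top] + 1
      }
      base
    }
  )
  structure(
    list(
      time_s = time_s, tau = profile$tau, eta = profile$eta,
      z_nm = profile$eta * length_nm,
      expected = expected, counts = counts, total = total,
      degenerate = n_total > 0 && all(expected < 1)
    ),
    class = "papm_molecule_profile"
  )
}

#' @export
print.papm_molecule_profile <- function(x, ...) {
  cat(sprintf(
    "Molecule profile at tau = %g%s: %d molecules in the projection%s\n",
    x$tau,
    if (is.na(x$time_s)) "" else sprintf(" (t = %g s)", x$time_s),
    x$total,
    if (x$degenerate) " [degenerate: < 1 expected molecule everywhere]" else ""
  ))
  print(data.frame(z_nm = x$z_nm, expected = signif(x$expected, 4),
                   count = x$counts), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.papm_molecule_profile <- function(x, ...) {
  data.frame(time_s = x$time_s, tau = x$tau, eta = x$eta, z_nm = x$z_nm,
             expected = x$expected, count = x$counts)
}

#' @export
plot.papm_molecule_profile <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = x$z_nm, xlab = "z (nm)",
                    ylab = "IP3 molecules",
                    main = sprintf("tau = %g, total = %d", x$tau, x$total), ...)
  invisible(x)
}

#' Molecule counts at the two faces
#'
#' `near_alpha()` returns the count at the source grid point (`eta = 0`, the
#' synaptic face); `near_beta()` the count at the far grid point (`eta = 1`,
#' the Ca2+ store face).
#'
#' @param mp A `papm_molecule_profile`.
#' @return Integer molecule count.
#' @export
near_alpha <- function(mp) {
  stopifnot(inherits(mp, "papm_molecule_profile"))
  mp$counts[1L]
}

#' @rdname near_alpha
#' @export
near_beta <- function(mp) {
  stopifnot(inherits(mp, "papm_molecule_profile"))
  mp$counts[length(mp$counts)]
}

#' Restrict a molecule profile to positions holding at least one molecule
#'
#' Positions whose pre-rounding expectation is below one molecule are
#' dropped: a fraction of a molecule at a position is not physically
#' interpretable. If no position survives, the returned (empty) profile is
#' flagged `degenerate` -- the regime where the continuum treatment stops
#' predicting where the few synthesized molecules sit.
#'
#' @param mp A `papm_molecule_profile`.
#' @return A filtered `papm_molecule_profile`.
#' @export
visible_profile <- function(mp) {
  stopifnot(inherits(mp, "papm_molecule_profile"))
  keep <- mp$expected >= 1
  out <- mp
  for (f in c("eta", "z_nm", "expected", "counts")) out[[f]] <- mp[[f]][keep]
  out$degenerate <- mp$degenerate || !any(keep)
  out
}

#' Default scenario grid behind the reference molecule table
#'
#' The 14 combinations of PLC copy number, specific activity and time for
#' which the model's molecule totals and near-store counts are tabulated.
#' The `time_s` column holds the working time actually used in the
#' arithmetic: the exact `tau * L^2 / Dab` values for `tau` = 0.1 (1/3000 s),
#' 0.3 (1 ms) and 1.5 (5 ms), and the 3-significant-figure rounding 2.67 ms
#' for `tau` = 0.8 (the exact 2.6667 ms and the rounded value give the same
#' near-store counts but different integer totals; the rounded value is the
#' one consistent with the reference totals).
#'
#' @return A data frame with columns `n_plc`, `kcat_per_s`, `time_s`, `tau`.
#' @export
table3_scenarios <- function() {
  t26 <- 2.67e-3
  rows <- rbind(
    c(100, 5000, 1 / 3000, 0.1),
    c(100, 5000, 1e-3, 0.3),
    c(10, 5000, 1e-3, 0.3),
    c(100, 1000, 1e-3, 0.3),
    c(100, 5000, t26, 0.8),
    c(10, 5000, t26, 0.8),
    c(1, 5000, t26, 0.8),
    c(100, 1000, t26, 0.8),
    c(10, 1000, t26, 0.8),
    c(100, 5000, 5e-3, 1.5),
    c(10, 5000, 5e-3, 1.5),
    c(1, 5000, 5e-3, 1.5),
    c(100, 1000, 5e-3, 1.5),
    c(10, 1000, 5e-3, 1.5)
  )
  out <- as.data.frame(rows)
  names(out) <- c("n_plc", "kcat_per_s", "time_s", "tau")
  out
}

#' Reference (total, near-beta) pairs for the default scenario grid
#'
#' The published integer molecule counts for the 14 default scenarios, used
#' by [check_table3()] as a golden reference.
#'
#' @return A data frame with columns `total_ip3` and `near_beta`.
#' @export
table3_reference <- function() {
  data.frame(
    total_ip3 = c(167, 500, 50, 100, 1335, 133, 13, 267, 27,
                  2500, 250, 25, 500, 50),
    near_beta = c(2, 29, 3, 6, 112, 11, 1, 22, 2, 225, 22, 2, 45, 4)
  )
}

#' End-to-end molecule table: synthesis, diffusion, allocation
#'
#' For each scenario row, synthesizes the IP3 total at the working time,
#' evaluates the dimensionless profile at the row's `tau`, allocates integer
#' molecules across the grid and reports the total and the count at the Ca2+
#' store face.
#'
#' @param scenarios A data frame as returned by [table3_scenarios()]; the
#'   `tau` column may be omitted, in which case it is derived from `time_s`.
#' @param geometry A [papm_geometry()].
#' @param constants A [papm_constants()].
#' @param n_points Allocation grid size (default 11).
#' @param pip2_budget PIP2 budget per scenario, molecules.
#' @return A data frame with columns `n_plc`, `kcat_per_s`, `time_s`, `tau`,
#'   `total_ip3`, `near_alpha`, `near_beta`, `degenerate`.
#' @export
#' @examples
#' tbl <- ip3_table()
#' tbl[tbl$tau == 1.5, ]
ip3_table <- function(scenarios = table3_scenarios(),
                      geometry = papm_geometry(),
                      constants = papm_constants(),
                      n_points = 11L, pip2_budget = 3000) {
  stopifnot(is.data.frame(scenarios))
  req <- c("n_plc", "kcat_per_s", "time_s")
  if (nrow(scenarios) > 0 && !all(req %in% names(scenarios))) {
    stop_invalid("scenarios must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(scenarios) == 0L) {
    return(data.frame(
      n_plc = numeric(), kcat_per_s = numeric(), time_s = numeric(),
      tau = numeric(), total_ip3 = numeric(), near_alpha = numeric(),
      near_beta = numeric(), degenerate = logical()
    ))
  }
  if (is.null(scenarios$tau)) {
    scenarios$tau <- time_to_tau(scenarios$time_s, geometry$length_nm,
                                 constants$dab_um2_s)
  }
  out <- lapply(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, ]
    scn <- synthesis_scenario(row$n_plc, row$kcat_per_s, pip2_budget)
    ntot <- total_ip3(scn, row$time_s, constants$degradation_horizon_s)
    prof <- dimensionless_profile(row$tau, n_points)
    mp <- allocate_molecules(prof, ntot, geometry$length_nm, row$time_s)
    data.frame(
      n_plc = row$n_plc, kcat_per_s = row$kcat_per_s, time_s = row$time_s,
      tau = row$tau, total_ip3 = mp$total, near_alpha = near_alpha(mp),
      near_beta = near_beta(mp), degenerate = mp$degenerate
    )
  })
  do.call(rbind, out)
}

#' Check a computed molecule table against the golden reference
#'
#' @param tbl Output of [ip3_table()] on the default scenario grid.
#' @param reference Reference pairs, by default [table3_reference()].
#' @return `TRUE` if all `(total_ip3, near_beta)` pairs match, else `FALSE`
#'   with a `mismatches` attribute holding the offending rows.
#' @export
check_table3 <- function(tbl = ip3_table(), reference = table3_reference()) {
  stopifnot(nrow(tbl) == nrow(reference))
  bad <- tbl$total_ip3 != reference$total_ip3 |
    tbl$near_beta != reference$near_beta
  if (any(bad)) {
    res <- FALSE
    attr(res, "mismatches") <- cbind(tbl[bad, ], expected = reference[bad, ])
    res
  } else {
    TRUE
  }
}
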