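#' PLC synthesis scenario at the source face
#'
#' IP3 is produced at the alpha face by phospholipase C (PLC) acting on the
#' local PIP2 pool. The model treats synthesis as zero-order: `n_plc`
#' enzymes each turning over `kcat_per_s` substrate molecules per second,
#' until the PIP2 budget (three ~1000-molecule clusters by default) is
#' exhausted, after which production stops abruptly. Up/down-regulation of
#' PLC and substrate-dependent slow-down are deliberately neglected; the
#' spanned copy-number/activity grid (1-100 PLC, 1000-5000 /s) is taken to
#' absorb them.
#'
#' @param n_plc Number of PLC molecules at the source face (>= 1).
#' @param kcat_per_s Specific catalytic activity per PLC, in 1/s.
#' @param pip2_budget Total PIP2 (hence maximal IP3) available, molecules.
#' @return An object of class `papm_scenario`.
#' @export
#' @examples
#' scn <- synthesis_scenario(100, 5000)
#' total_ip3(scn, 5e-3)  # 2500 molecules after 5 ms
#' depletion_time(scn)   # 6 ms to exhaust the PIP2 pool
synthesis_scenario <- function(n_plc, kcat_per_s, pip2_budget = 3000) {
  if (!is.numeric(n_plc) || length(n_plc) != 1L || n_plc < 1 ||
      n_plc != round(n_plc)) {
    stop_invalid("n_plc must be an integer >= 1")
  }
  check_positive(kcat_per_s, "kcat_per_s")
  check_nonnegative(pip2_budget, "pip2_budget")
  structure(
    list(n_plc = n_plc, kcat_per_s = kcat_per_s, pip2_budget = pip2_budget),
    class = "papm_scenario"
  )
}

#' @export
print.papm_scenario <- function(x, ...) {
  cat(sprintf("PLC scenario: %d PLC at %g/s, PIP2 budget %g molecules\n",
              x$n_plc, x$kcat_per_s, x$pip2_budget))
  invisible(x)
}

#' Total IP3 synthesized by time t
#'
#' `min(n_plc * kcat * t, pip2_budget)`, real-valued (integer rounding is
#' applied downstream, see [allocate_molecules()]). No degradation is
#' subtracted, so the value is only meaningful for times below the
#' degradation horizon; a warning is emitted beyond it.
#'
#' @param scn A [synthesis_scenario()].
#' @param t Time(s) since PLC activation, seconds (vectorized).
#' @param degradation_horizon_s Warn when `t` exceeds this (default 0.8 s).
#' @return Synthesized IP3 count(s), capped at the PIP2 budget.
#' @export
total_ip3 <- function(scn, t, degradation_horizon_s = 0.8) {
  stopifnot(inherits(scn, "papm_scenario"))
  check_nonnegative(t, "t")
  if (any(t > degradation_horizon_s)) {
    warning(sprintf(
      "t exceeds the %g s degradation horizon; the no-removal assumption breaks down",
      degradation_horizon_s
    ))
  }
  pmin(scn$n_plc * scn$kcat_per_s * t, scn$pip2_budget)
}

#' Time for PLC to exhaust the PIP2 budget
#'
#' `pip2_budget / (n_plc * kcat)`. Even a single PLC at 5000/s empties the
#' default 3000-molecule pool in 0.6 s, below the 0.8 s degradation horizon
#' -- the internal consistency check behind ignoring removal.
#'
#' @param scn A [synthesis_scenario()].
#' @return Depletion time in seconds.
#' @export
depletion_time <- function(scn) {
  stopifnot(inherits(scn, "papm_scenario"))
  scn$pip2_budget / (scn$n_plc * scn$kcat_per_s)
}
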