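#' @keywords internal
"_PACKAGE"

## Error helper: all user-facing validation failures share one condition class
## so callers (and the CLI) can distinguish bad parameters from bugs.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = "papm_invalid_parameter"))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(name, " must be a finite positive number")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x < 0)) {
    stop_invalid(name, " must be a finite non-negative number")
  }
  invisible(x)
}

#' Round a molecule count to the nearest integer
#'
#' Nearest-integer rounding with exact halves rounded down, the convention
#' under which the package's integer molecule tables are internally
#' consistent (e.g. 133.5 -> 133 while 26.7 -> 27 and 224.52 -> 225).
#' A small guard absorbs floating-point representation noise at ties.
#'
#' @param x Numeric vector of non-negative real-valued counts.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_count(c(40.65, 224.52, 133.5, 26.7))
round_count <- function(x) {
  check_nonnegative(x, "x")
  floor(x + 0.5 - sqrt(.Machine$double.eps))
}

## Complementary error function via the normal CDF (erfc(x) = 2*pnorm(-x*sqrt(2))).
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Write a results data frame to CSV and/or JSON
#'
#' Shared exporter for the package's tabular outputs (conversion tables,
#' concentration profiles, molecule tables, parameter sweeps).
#'
#' @param x A data frame.
#' @param csv,json Optional file paths; each format is written only when its
#'   path is non-`NULL`.
#' @return `x`, invisibly.
#' @export
export_results <- function(x, csv = NULL, json = NULL) {
  stopifnot(is.data.frame(x))
  if (!is.null(csv)) utils::write.csv(x, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(x, json, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  invisible(x)
}
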