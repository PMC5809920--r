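# Brute-force eigenfunction sum: fixed 500 terms, no adaptive truncation, no
# clamping. Kept deliberately independent of phi_series() internals.
brute_phi <- function(tau, eta, n_terms = 500L) {
  s <- 0
  for (n in 0:(n_terms - 1L)) {
    k <- 2 * n + 1
    s <- s + exp(-k^2 * pi^2 * tau / 4) * sin(k * pi * eta / 2) / k
  }
  1 - 4 / pi * s
}

# Base-R complementary error function, independent of the package's internal.
ref_erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
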