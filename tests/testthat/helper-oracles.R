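# Independent oracles and fixture builders used across the suite.

# Dense midpoint-rule quadrature of the sin-weighted Hermans moment for
# an intensity function I(chi) given in radians on [0, pi/2]. Kept
# independent of the package's trapezoid-on-profile implementation.
of_oracle <- function(I_fun, n = 1e5) {
  x <- (seq_len(n) - 0.5) * (pi / 2) / n
  I <- I_fun(x)
  cos2 <- sum(I * sin(x) * cos(x)^2) / sum(I * sin(x))
  (3 * cos2 - 1) / 2
}

# Azimuthal profile (full circle, 1-degree bins) with all intensity in
# one bin.
delta_profile <- function(angle, height = 100) {
  chi <- 0:359
  I <- numeric(360)
  I[chi == angle] <- height
  data.frame(chi = chi, I = I, valid = TRUE)
}

# Full-circle axial von Mises profile about chi_pref (degrees).
vm_profile <- function(kappa, chi_pref = 0, scale = 1) {
  chi <- 0:359
  data.frame(chi = chi,
             I = scale * exp(kappa * cos(2 * (chi - chi_pref) * pi / 180)),
             valid = TRUE)
}

# Direct unbiased autocorrelation; returns the lag of the first interior
# local maximum (lag >= 2). Independent re-derivation of the estimator's
# core for cross-checks on known signals.
acf_first_peak <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  ac <- vapply(0:(n - 2), function(k)
    sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k), numeric(1))
  for (k in 3:(length(ac) - 1))
    if (ac[k] > ac[k - 1] && ac[k] >= ac[k + 1] && ac[k] > 0) return(k - 1L)
  NA_integer_
}

# Centered DFT frequencies (cycles per sample spacing d), sorted.
fftshift_freqs <- function(n, d = 1) {
  sort(c(seq.int(0, ceiling(n / 2) - 1), seq.int(-floor(n / 2), -1)) / (n * d))
}

# Tiny noiseless pattern used by several reduction tests.
toy_pattern <- function(...) {
  simulate_saxs_pattern(saxs_sim_config(noise = FALSE, ...))
}
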