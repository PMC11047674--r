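# Independent oracles, written from the definitions rather than the package
# implementation they check.

# Direct Riemann-sum evaluation of the CWT:
#   WT(a, b) = (1/sqrt(a/fs)) * sum_t x[t] * conj(psi((t - b)/a)) / fs
# with the full window as support (no kernel truncation). psi is the
# first-order complex Gaussian, written out independently here.
oracleCwt <- function(x, fs, scales) {
  psi <- function(u) {
    (1 / sqrt(2 * sqrt(pi / 2))) * (-2 * u - 1i) * exp(-u^2 - 1i * u)
  }
  n <- length(x)
  t <- seq_len(n) - 1
  mags <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    for (b in seq_len(n) - 1) {
      w <- sum(x * Conj(psi((t - b) / a))) / (fs * sqrt(a / fs))
      mags[si, b + 1] <- Mod(w)
    }
  }
  mags
}

# Analytic squared magnitude response of an order-n analog Butterworth
# band-pass prototype; filtfilt applies the filter twice, so the expected
# steady-state amplitude of a sinusoid is |H|^2.
oracleButterBandpassGain <- function(f, low, high, order) {
  eps <- (f^2 - low * high) / (f * (high - low))
  1 / (1 + eps^(2 * order))
}

# Steady-state amplitude of a filtered sinusoid, measured away from the
# filter edge transients.
steadyAmplitude <- function(y, fs) {
  mid <- y[round(length(y) * 0.3):round(length(y) * 0.7)]
  (max(mid) - min(mid)) / 2
}
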