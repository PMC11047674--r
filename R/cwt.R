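## Complex Gaussian wavelet of order 1 ("cgau1"):
## psi(t) = C1 * d/dt[exp(-t^2) * exp(-i t)],  C1 chosen so ||psi||_2 = 1.
## d/dt[exp(-t^2 - i t)] = (-2t - i) exp(-t^2 - i t);
## ||psi'||^2 = int (4t^2 + 1) exp(-2 t^2) dt = 2 sqrt(pi/2).
cgau1 <- function(t) {
  C1 <- 1 / sqrt(2 * sqrt(pi / 2))
  C1 * (-2 * t - 1i) * exp(-t^2 - 1i * t)
}

#' Center frequency of the cgau1 wavelet
#'
#' The pseudo-frequency of scale `a` at sampling rate `fs` is
#' `fc * fs / a`. `fc` is defined so that a pure tone attains its maximal
#' L2-normalised CWT magnitude at the scale whose pseudo-frequency equals
#' the tone frequency: maximising `sqrt(a) * |psihat(a w)|` with
#' `|psihat(W)| ~ W exp(-(W-1)^2/4)` gives `W* = (1 + sqrt(13))/2` rad,
#' i.e. `fc = (1 + sqrt(13)) / (4 pi) ~ 0.3665` cycles.
#'
#' @return the center frequency in cycles per unit of wavelet time.
#' @export
cgau1CenterFrequency <- function() (1 + sqrt(13)) / (4 * pi)

#' Default scale grid spanning the filter passband
#'
#' 64 logarithmically spaced scales whose pseudo-frequencies span 0.5-8 Hz
#' (the band-pass filter passband), ordered by increasing scale.
#'
#' @param fs sampling rate in Hz.
#' @param nScales number of scales.
#' @param freqRange pseudo-frequency span in Hz.
#' @return increasing numeric vector of scales, in samples.
#' @export
defaultScales <- function(fs, nScales = 64, freqRange = c(0.5, 8)) {
  f <- exp(seq(log(freqRange[2]), log(freqRange[1]), length.out = nScales))
  cgau1CenterFrequency() * fs / f
}

#' Pseudo-frequencies of a scalogram's scale grid
#'
#' @param s a [Scalogram-class].
#' @return numeric vector of pseudo-frequencies in Hz, one per scale row.
#' @export
pseudoFrequencies <- function(s) {
  stopifnot(is(s, "Scalogram"))
  cgau1CenterFrequency() * s@fs / s@scales
}

#' Continuous wavelet transform scalogram of one window
#'
#' Computes `WT(a, b) = (1/sqrt(a_sec)) * sum_t x[t] conj(psi((t-b)/a)) / fs`
#' on the sample grid for every scale, via FFT-based linear convolution
#' (zero beyond the window ends; the wavelet is truncated at `|t/a| <= 6`
#' where it has decayed below 1e-15). The wavelet is complex-valued, so the
#' returned scalogram holds the magnitudes `|WT|`.
#'
#' @param window numeric vector (one 5 s segment), length >= 2.
#' @param fs sampling rate in Hz.
#' @param scales positive scales in samples; defaults to [defaultScales()].
#' @param wavelet wavelet name; only `"cgau1"` is supported.
#' @return a [Scalogram-class].
#' @examples
#' t <- seq(0, 5, by = 1/200)[-1]
#' s <- cwtScalogram(sin(2 * pi * 2 * t), fs = 200)
#' s
#' @export
cwtScalogram <- function(window, fs, scales = NULL, wavelet = "cgau1") {
  if (!identical(wavelet, "cgau1"))
    stop("unsupported wavelet: ", wavelet)
  n <- length(window)
  if (n < 2L) stop("window must contain at least 2 samples")
  if (is.null(scales)) scales <- defaultScales(fs)
  if (any(scales <= 0)) stop("parameter error: scales must be positive")
  scales <- sort(scales)
  mags <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    M <- ceiling(6 * a)
    m <- (-M):M
    g <- Conj(cgau1(m / a)) / (fs * sqrt(a / fs))
    nfft <- 2^ceiling(log2(n + 2 * M + 1))
    xp <- complex(nfft)
    xp[seq_len(n)] <- window
    # place the flipped kernel g(-m) circularly so that
    # ifft(fft(x) * fft(q))[b] = sum_t x[t] g[t-b]
    q <- complex(nfft)
    q[((-M):M) %% nfft + 1L] <- rev(g)
    wt <- stats::fft(stats::fft(xp) * stats::fft(q), inverse = TRUE)[seq_len(n)] / nfft
    mags[si, ] <- Mod(wt)
  }
  new("Scalogram", magnitudes = mags, scales = scales,
      wavelet = wavelet, fs = fs)
}
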