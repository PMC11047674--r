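#' Zero-phase Butterworth band-pass filter
#'
#' Applies a second-order 0.5-8 Hz Butterworth band-pass forward and
#' backward (`signal::filtfilt`), removing DC and high-frequency noise
#' without shifting pulse landmarks.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz; must exceed twice the upper edge.
#' @param low,high band edges in Hz.
#' @param order Butterworth prototype order.
#' @return filtered signal, same length as `x`.
#' @export
bandpassFilter <- function(x, fs, low = 0.5, high = 8, order = 2) {
  if (fs <= 2 * high)
    stop("sampling error: fs must exceed twice the upper band edge")
  if (length(x) <= 3 * order)
    stop("signal too short for the requested filter order")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # remove the mean first: DC lies outside the passband anyway, and a large
  # offset would otherwise excite edge transients in the forward-backward
  # pass (filtfilt extends the signal with zeros)
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Z-score normalisation
#'
#' @param x numeric signal (non-constant).
#' @return `(x - mean(x)) / sd(x)`.
#' @export
normalizeSignal <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: cannot normalize a constant signal")
  (x - mean(x)) / s
}

#' Sliding-window segmentation
#'
#' Cuts a signal into windows of `win` seconds sliding by `stride` seconds.
#' No padding: the count is `floor((len/fs - win)/stride) + 1`.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param win window length in seconds.
#' @param stride hop in seconds.
#' @return matrix `win*fs x nWindows`, one window per column.
#' @export
segmentWindows <- function(x, fs, win = 5, stride = 1) {
  winLen <- round(win * fs)
  hop <- round(stride * fs)
  if (length(x) < winLen)
    stop("length error: signal shorter than one window")
  count <- floor((length(x) - winLen) / hop) + 1L
  starts <- (seq_len(count) - 1L) * hop + 1L
  vapply(starts, function(s) x[s:(s + winLen - 1L)], numeric(winLen))
}

#' Filter, normalise and window one record
#'
#' Runs the per-channel pipeline (band-pass filter, per-record z-score,
#' simultaneous windowing of all four channels) and returns an aligned
#' [WindowSet-class]; window i covers identical sample indices in every
#' channel, and every window inherits the record's (SBP, DBP) label.
#'
#' @param record an [MWPPGRecord-class].
#' @param win,stride window length and hop in seconds.
#' @param low,high,order band-pass settings, see [bandpassFilter()].
#' @return a [WindowSet-class].
#' @export
preprocessRecord <- function(record, win = 5, stride = 1,
                             low = 0.5, high = 8, order = 2) {
  stopifnot(is(record, "MWPPGRecord"))
  fs <- record@fs
  filtered <- apply(record@samples, 2, function(ch)
    normalizeSignal(bandpassFilter(ch, fs, low, high, order)))
  segs <- lapply(1:4, function(k) segmentWindows(filtered[, k], fs, win, stride))
  nw <- ncol(segs[[1]])
  windows <- array(unlist(segs), dim = c(nrow(segs[[1]]), nw, 4))
  new("WindowSet", windows = windows, subjectId = record@subjectId,
      windowIndex = seq_len(nw), fs = fs,
      sbp = record@sbp, dbp = record@dbp)
}

#' Quality rule for abnormal-segment rejection
#'
#' @param max_flatline_fraction maximum tolerated fraction of flat
#'   (zero-derivative) samples in a window.
#' @param amplitude_z_limit maximum tolerated absolute amplitude of the
#'   record-normalised signal.
#' @param min_periodicity minimum autocorrelation at the best lag in the
#'   physiological beat-period range (0.4-1.5 s).
#' @return a validated rule of class `mwppgQualityRule`.
#' @export
qualityRule <- function(max_flatline_fraction = 0.1,
                        amplitude_z_limit = 25,
                        min_periodicity = 0.3) {
  if (max_flatline_fraction < 0 || max_flatline_fraction > 1)
    stop("max_flatline_fraction must lie in [0, 1]")
  if (min_periodicity < 0 || min_periodicity > 1)
    stop("min_periodicity must lie in [0, 1]")
  structure(list(max_flatline_fraction = max_flatline_fraction,
                 amplitude_z_limit = amplitude_z_limit,
                 min_periodicity = min_periodicity),
            class = "mwppgQualityRule")
}

windowViolation <- function(x, fs, rule) {
  rng <- diff(range(x))
  flat <- mean(abs(diff(x)) <= 1e-7 * max(rng, 1e-12))
  if (rng == 0 || flat > rule$max_flatline_fraction) return("flatline")
  if (max(abs(x)) > rule$amplitude_z_limit) return("amplitude")
  lags <- max(2L, round(0.4 * fs)):min(length(x) - 2L, round(1.5 * fs))
  ac <- stats::acf(x, lag.max = max(lags), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  if (max(ac[lags + 1L]) < rule$min_periodicity) return("aperiodic")
  NA_character_
}

#' Reject abnormal windows, keeping the four channels aligned
#'
#' A window is dropped from ALL channels if ANY channel violates the rule,
#' preserving the simultaneous four-wavelength alignment.
#'
#' @param ws a [WindowSet-class].
#' @param rule a rule from [qualityRule()].
#' @return list with `windows` (the retained [WindowSet-class]) and
#'   `dropLog`, a data frame (`subject`, `window`, `channel`, `reason`);
#'   an empty retained set is allowed and flagged in the log.
#' @export
rejectAbnormal <- function(ws, rule = qualityRule()) {
  stopifnot(is(ws, "WindowSet"))
  d <- dim(ws@windows)
  if (d[2] == 0L) stop("rejectAbnormal requires a non-empty WindowSet")
  log <- list()
  bad <- logical(d[2])
  for (w in seq_len(d[2])) {
    for (k in 1:4) {
      reason <- windowViolation(ws@windows[, w, k], ws@fs, rule)
      if (!is.na(reason)) {
        bad[w] <- TRUE
        log[[length(log) + 1L]] <- data.frame(
          subject = ws@subjectId, window = ws@windowIndex[w],
          channel = k, reason = reason, stringsAsFactors = FALSE)
      }
    }
  }
  dropLog <- if (length(log)) do.call(rbind, log) else
    data.frame(subject = character(), window = integer(),
               channel = integer(), reason = character(),
               stringsAsFactors = FALSE)
  keep <- which(!bad)
  out <- new("WindowSet",
             windows = ws@windows[, keep, , drop = FALSE],
             subjectId = ws@subjectId,
             windowIndex = ws@windowIndex[keep],
             fs = ws@fs, sbp = ws@sbp, dbp = ws@dbp)
  if (length(keep) == 0L)
    warning("all windows rejected for subject ", ws@subjectId)
  list(windows = out, dropLog = dropLog)
}
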