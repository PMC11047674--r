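#' Simulation configuration for synthetic multi-wavelength PPG cohorts
#'
#' Defines the acquisition protocol the generator emulates: 200 Hz sampling,
#' 60 s per subject, four wavelength channels with correlated beat morphology,
#' per-channel amplitude gains and a monotone dicrotic-prominence gradient
#' (deeper-penetrating wavelengths show a stronger dicrotic wave), baseline
#' wander, additive noise, and SBP/DBP labels linked deterministically to the
#' beat morphology.
#'
#' The blood-pressure link is affine: SBP and DBP are linear in heart rate,
#' the mean realised dicrotic/systolic amplitude ratio across the four
#' channels, the cross-channel dicrotic contrast (Channel 4 minus Channel 1
#' ratio) and the dicrotic notch delay, plus Gaussian label noise
#' (`label_noise_sd`, default 2 mmHg). Because each channel's ratio carries
#' independent jitter, the channel-mean and the cross-channel contrast are
#' only identifiable from all four channels jointly, which is what gives
#' multi-wavelength fusion a genuine information advantage over any single
#' channel.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param hr_range heart-rate interval, beats/min.
#' @param sbp_range,dbp_range admissible label intervals, mmHg; labels are
#'   censored into these ranges.
#' @param noise_sd additive white-noise amplitude relative to the beat
#'   amplitude.
#' @param wander_amp baseline-wander amplitude relative to the beat
#'   amplitude (wander frequency 0.08-0.25 Hz, below the filter passband).
#' @param channel_gains four positive per-wavelength amplitude factors.
#' @param hypertensive_fraction expected fraction of subjects drawn from the
#'   hypertensive morphology regime (default 0.407, i.e. 66/162).
#' @param label_noise_sd standard deviation of the Gaussian label noise in
#'   mmHg; set to 0 for a noise-free parameter-recovery cohort.
#' @param dicrotic_gradient per-channel additive offsets of the dicrotic
#'   ratio, strictly increasing across channels 1..4.
#' @param dicrotic_jitter_sd per-channel independent jitter of the dicrotic
#'   ratio.
#' @param seed integer seed; together with the subject index it fully
#'   determines each record (subject-level counter-based substreams, so a
#'   subject's record does not depend on the cohort size).
#' @return a validated configuration list of class `mwppgSimConfig`.
#' @export
simConfig <- function(n_subjects = 1L, fs = 200, duration = 60,
                      hr_range = c(55, 100),
                      sbp_range = c(80, 200), dbp_range = c(45, 120),
                      noise_sd = 0.02, wander_amp = 0.25,
                      channel_gains = c(1.0, 0.9, 0.85, 0.8),
                      hypertensive_fraction = 0.407,
                      label_noise_sd = 2,
                      dicrotic_gradient = c(-0.09, -0.03, 0.03, 0.09),
                      dicrotic_jitter_sd = 0.06,
                      seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), fs = fs, duration = duration,
    hr_range = hr_range, sbp_range = sbp_range, dbp_range = dbp_range,
    noise_sd = noise_sd, wander_amp = wander_amp,
    channel_gains = channel_gains,
    hypertensive_fraction = hypertensive_fraction,
    label_noise_sd = label_noise_sd,
    dicrotic_gradient = dicrotic_gradient,
    dicrotic_jitter_sd = dicrotic_jitter_sd,
    seed = as.integer(seed)
  )
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 1L)
    stop("invalid simulation configuration: n_subjects must be >= 1")
  if (cfg$fs <= 0) stop("invalid simulation configuration: fs must be > 0")
  if (cfg$duration <= 0)
    stop("invalid simulation configuration: duration must be > 0")
  for (nm in c("hr_range", "sbp_range", "dbp_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] >= r[2] || any(r <= 0))
      stop("invalid simulation configuration: ", nm,
           " must be an increasing positive interval")
  }
  if (length(cfg$channel_gains) != 4L || any(cfg$channel_gains <= 0))
    stop("invalid simulation configuration: channel_gains must be 4 positive values")
  if (cfg$hypertensive_fraction < 0 || cfg$hypertensive_fraction > 1)
    stop("invalid simulation configuration: hypertensive_fraction must be in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$wander_amp < 0 || cfg$label_noise_sd < 0)
    stop("invalid simulation configuration: noise and wander amplitudes must be >= 0")
  if (length(cfg$dicrotic_gradient) != 4L ||
      is.unsorted(cfg$dicrotic_gradient, strictly = TRUE))
    stop("invalid simulation configuration: dicrotic_gradient must be 4 increasing values")
  class(cfg) <- "mwppgSimConfig"
  cfg
}

# Counter-based per-subject seed: reproducible per (seed, subject), and
# independent of how many other subjects the cohort holds.
subjectSeed <- function(seed, subjectIndex) {
  as.integer((abs(as.numeric(seed)) %% 1e5 * 97561 +
              as.numeric(subjectIndex) * 7919) %% 2147483647)
}

# Affine morphology -> blood pressure link. `ratios` are the four realised
# per-channel dicrotic/systolic amplitude ratios.
bpFromMorphology <- function(hr, ratios, notchDelay, labelNoise, cfg) {
  rbar <- mean(ratios)
  contrast <- ratios[4] - ratios[1]
  gradSpan <- cfg$dicrotic_gradient[4] - cfg$dicrotic_gradient[1]
  sbp <- 25 + 0.45 * hr + 110 * rbar + 60 * (contrast - gradSpan) -
    30 * notchDelay + labelNoise[1]
  dbp <- 41 + 0.225 * hr + 38.5 * rbar + 24 * (contrast - gradSpan) -
    12 * notchDelay + labelNoise[2]
  sbp <- min(max(sbp, cfg$sbp_range[1]), cfg$sbp_range[2])
  dbp <- min(max(dbp, cfg$dbp_range[1]), cfg$dbp_range[2])
  dbp <- min(dbp, sbp - 15)
  dbp <- max(dbp, cfg$dbp_range[1])
  c(sbp = round(sbp), dbp = round(dbp))
}

drawBeatParams <- function(cfg) {
  hyper <- stats::runif(1) < cfg$hypertensive_fraction
  hr <- stats::runif(1, cfg$hr_range[1], cfg$hr_range[2])
  baseRatio <- if (hyper) stats::runif(1, 0.80, 1.00) else
    stats::runif(1, 0.25, 0.55)
  notchDelay <- stats::runif(1, 0.22, 0.34)
  jitter <- stats::rnorm(4, 0, cfg$dicrotic_jitter_sd)
  ratios <- pmin(pmax(baseRatio + cfg$dicrotic_gradient + jitter, 0.05), 1.3)
  list(
    hyperRegime = hyper, hr = hr, baseRatio = baseRatio, ratios = ratios,
    notchDelay = notchDelay,
    systolicWidth = stats::runif(1, 0.08, 0.10),
    dicroticWidth = stats::runif(1, 0.11, 0.15)
  )
}

# Two-Gaussian beat train for one channel: a systolic wave of unit amplitude
# and a dicrotic wave of relative amplitude `ratio`, delayed by the notch
# delay. Each beat only touches its local support.
beatTrain <- function(n, fs, hr, ratio, notchDelay, sw, dw) {
  x <- numeric(n)
  period <- 60 / hr
  t <- (seq_len(n) - 1) / fs
  onsets <- seq(0, (n - 1) / fs + period, by = period)
  halo <- notchDelay + 4 * dw
  for (b in onsets) {
    lo <- max(1L, floor((b - 4 * sw) * fs) + 1L)
    hi <- min(n, ceiling((b + halo) * fs) + 1L)
    if (lo > n || hi < 1L) next
    tt <- t[lo:hi]
    x[lo:hi] <- x[lo:hi] +
      exp(-(tt - b)^2 / (2 * sw^2)) +
      ratio * exp(-(tt - b - notchDelay)^2 / (2 * dw^2))
  }
  x
}

#' Simulate one subject's four-wavelength PPG record
#'
#' Generates a labelled [MWPPGRecord-class]: each beat is a two-Gaussian
#' pulse (systolic plus dicrotic wave); channel k scales the amplitude by
#' `channel_gains[k]` and increases the dicrotic prominence monotonically
#' with k; baseline wander and white noise are added; labels follow the
#' affine morphology link described in [simConfig()]. Output is fully
#' reproducible given `(cfg$seed, subjectIndex)`.
#'
#' @param cfg an `mwppgSimConfig` from [simConfig()].
#' @param subjectIndex subject number in `1..cfg$n_subjects`.
#' @return a labelled [MWPPGRecord-class].
#' @examples
#' rec <- simulateRecord(simConfig(n_subjects = 1, duration = 10), 1)
#' rec
#' @export
simulateRecord <- function(cfg, subjectIndex) {
  if (!inherits(cfg, "mwppgSimConfig")) cfg <- do.call(simConfig, cfg)
  subjectIndex <- as.integer(subjectIndex)
  if (subjectIndex < 1L || subjectIndex > cfg$n_subjects)
    stop("subjectIndex must lie in 1..n_subjects")
  n <- round(cfg$fs * cfg$duration)
  withr::with_seed(subjectSeed(cfg$seed, subjectIndex), {
    bp <- drawBeatParams(cfg)
    labelNoise <- stats::rnorm(2, 0, c(1, 0.75) * cfg$label_noise_sd)
    wanderFreq <- stats::runif(1, 0.08, 0.25)
    wanderPhase <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1) / cfg$fs
    wander <- sin(2 * pi * wanderFreq * t + wanderPhase)
    samples <- matrix(0, n, 4)
    for (k in 1:4) {
      gain <- cfg$channel_gains[k]
      pulse <- beatTrain(n, cfg$fs, bp$hr, bp$ratios[k], bp$notchDelay,
                         bp$systolicWidth, bp$dicroticWidth)
      samples[, k] <- gain * (pulse + cfg$wander_amp * wander +
                                cfg$noise_sd * stats::rnorm(n) + 10)
    }
    bpv <- bpFromMorphology(bp$hr, bp$ratios, bp$notchDelay, labelNoise, cfg)
    rec <- new("MWPPGRecord",
      subjectId = sprintf("S%03d", subjectIndex),
      samples = samples, fs = cfg$fs,
      sbp = bpv[["sbp"]], dbp = bpv[["dbp"]],
      hypertensive = bpv[["sbp"]] >= 130 || bpv[["dbp"]] >= 90
    )
    attr(rec@samples, "morphology") <- bp
    rec
  })
}

#' Simulate a labelled cohort
#'
#' @param cfg an `mwppgSimConfig` from [simConfig()].
#' @return a list with `records` (list of [MWPPGRecord-class]) and `labels`,
#'   a data frame with one row per subject
#'   (`subject_id`, `sbp`, `dbp`, `hypertensive`).
#' @examples
#' cohort <- simulateCohort(simConfig(n_subjects = 3, duration = 6))
#' cohort$labels
#' @export
simulateCohort <- function(cfg) {
  if (!inherits(cfg, "mwppgSimConfig")) cfg <- do.call(simConfig, cfg)
  records <- lapply(seq_len(cfg$n_subjects), function(i)
    simulateRecord(cfg, i))
  labels <- data.frame(
    subject_id = vapply(records, subjectId, character(1)),
    sbp = vapply(records, function(r) r@sbp, numeric(1)),
    dbp = vapply(records, function(r) r@dbp, numeric(1)),
    hypertensive = vapply(records, function(r) r@hypertensive, logical(1)),
    stringsAsFactors = FALSE
  )
  list(records = records, labels = labels)
}
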