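test_that("the band-pass filter suppresses DC and out-of-band tones", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)

  # constant input: DC is outside the passband
  y <- bandpassFilter(rep(3, length(t)), fs)
  expect_lt(max(abs(y)), 1e-6 * 3)

  # 4 Hz tone: in-band, amplitude preserved (analytic oracle |H|^2)
  y4 <- bandpassFilter(sin(2 * pi * 4 * t), fs)
  amp4 <- steadyAmplitude(y4, fs)
  expect_gt(amp4, 0.9)
  expect_lt(amp4, 1.1)
  expect_lt(abs(amp4 - oracleButterBandpassGain(4, 0.5, 8, 2)), 0.05)

  # 50 Hz tone: stop band
  y50 <- bandpassFilter(sin(2 * pi * 50 * t), fs)
  expect_lt(steadyAmplitude(y50, fs), 0.1)
})

test_that("filtering is linear", {
  fs <- 200
  withr::with_seed(1, {
    x <- rnorm(2000)
    y <- rnorm(2000)
  })
  lhs <- bandpassFilter(2 * x + 3 * y, fs)
  rhs <- 2 * bandpassFilter(x, fs) + 3 * bandpassFilter(y, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("the filter refuses impossible sampling rates", {
  expect_error(bandpassFilter(rnorm(100), fs = 10), "sampling error")
})

test_that("normalisation is exact and affine-invariant", {
  withr::with_seed(2, x <- rnorm(500, 7, 3))
  z <- normalizeSignal(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)
  expect_equal(normalizeSignal(2.5 * x + 11), z, tolerance = 1e-12)
  expect_error(normalizeSignal(rep(4, 100)), "degenerate")
})

test_that("window counts follow the sliding-window arithmetic", {
  fs <- 200
  x <- rnorm(60 * fs)
  w <- segmentWindows(x, fs, win = 5, stride = 1)
  expect_equal(dim(w), c(1000L, 56L))  # (60-5)/1 + 1

  expect_equal(ncol(segmentWindows(rnorm(1000), fs)), 1L)
  expect_error(segmentWindows(rnorm(999), fs), "length error")

  # windows are exact slices, no padding
  expect_equal(w[, 2], x[201:1200])
})

test_that("four-channel windows stay aligned and inherit labels", {
  rec <- simulateRecord(tinySimConfig(n = 1, duration = 12), 1)
  ws <- preprocessRecord(rec, stride = 1)
  expect_equal(nWindows(ws), 8L)
  expect_equal(unname(bpLabels(ws)), unname(bpLabels(rec)))

  # window i covers identical sample indices in all channels: recompute one
  # channel independently
  f3 <- normalizeSignal(bandpassFilter(ppgSamples(rec)[, 3],
                                       sampleRate(rec)))
  expect_equal(ws@windows[, 4, 3], f3[601:1600])
})

test_that("clean simulated windows are fully retained by the default rule", {
  cfg <- tinySimConfig(n = 2, duration = 30, noise_sd = 0, wander_amp = 0)
  for (i in 1:2) {
    ws <- preprocessRecord(simulateRecord(cfg, i), stride = 1)
    res <- rejectAbnormal(ws)
    expect_equal(nWindows(res$windows), nWindows(ws))
    expect_equal(nrow(res$dropLog), 0L)
  }
})

test_that("one bad channel drops the window from all four channels", {
  rec <- simulateRecord(tinySimConfig(n = 1, duration = 14), 1)
  ws <- preprocessRecord(rec, stride = 1)
  ws@windows[, 5, 2] <- 0  # flatline channel 2 of window 5
  res <- rejectAbnormal(ws)
  expect_false(5L %in% res$windows@windowIndex)
  expect_equal(nWindows(res$windows), nWindows(ws) - 1L)
  expect_true(all(res$dropLog$window == 5L))
  expect_true("flatline" %in% res$dropLog$reason)
})

test_that("an all-flat window set rejects everything with a warning", {
  ws <- new("WindowSet",
            windows = array(1, c(1000, 2, 4)), subjectId = "flat",
            windowIndex = 1:2, fs = 200, sbp = 120, dbp = 80)
  expect_warning(res <- rejectAbnormal(ws), "all windows rejected")
  expect_equal(nWindows(res$windows), 0L)
})
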