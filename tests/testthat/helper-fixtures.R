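# Shared tiny fixtures, built in code at test time.

tinySimConfig <- function(n = 2L, duration = 10, seed = 42L, ...) {
  simConfig(n_subjects = n, duration = duration, seed = seed, ...)
}

tinyModelConfig <- function(variant = "fused12") {
  modelConfig(variant = variant, convBlocks = 2L, convChannels = c(3L, 4L),
              lstmHidden = 5L, fcSizes = c(6L, 2L))
}

randomInput <- function(n, channels, size = 8L, seed = 1L) {
  withr::with_seed(seed, array(stats::rnorm(size * size * n * channels),
                               c(size, size, n, channels)))
}

# Memoised medium cohort + dataset shared across heavy test files.
.sharedEnv <- new.env(parent = emptyenv())

sharedCohort <- function() {
  if (is.null(.sharedEnv$cohort)) {
    .sharedEnv$cfg <- simConfig(n_subjects = 60, label_noise_sd = 0,
                                seed = 11)
    .sharedEnv$cohort <- simulateCohort(.sharedEnv$cfg)
  }
  .sharedEnv$cohort
}

sharedDataset <- function() {
  if (is.null(.sharedEnv$dataset))
    .sharedEnv$dataset <- buildTrialDataset(sharedCohort(), imgSize = 32,
                                            stride = 3)
  .sharedEnv$dataset
}

# Independent recomputation of the fixed colormap origin.
viridisLUTForTest <- function() {
  t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))) / 255
}
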