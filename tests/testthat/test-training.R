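makeMeta <- function(nSubjects, windowsEach = 3L) {
  data.frame(
    subject_id = rep(sprintf("S%03d", seq_len(nSubjects)),
                     each = windowsEach),
    window = rep(seq_len(windowsEach), nSubjects),
    sbp = rep(rnorm(nSubjects, 120, 10), each = windowsEach),
    dbp = rep(rnorm(nSubjects, 75, 6), each = windowsEach),
    stringsAsFactors = FALSE
  )
}

test_that("splits are 80/20, deterministic, and subject-disjoint", {
  withr::with_seed(1, meta <- makeMeta(100, 1L))
  tcfg <- trainConfig(seed = 7)
  s1 <- makeSplits(meta, tcfg)
  s2 <- makeSplits(meta, tcfg)
  expect_identical(s1, s2)
  expect_equal(length(s1$train), 80L)
  expect_equal(length(s1$test), 20L)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_length(intersect(s1$trainSubjects, s1$testSubjects), 0)
  expect_equal(sort(unique(s1$foldOf)), 1:10)

  # windows of one subject never straddle the partition at record level
  withr::with_seed(2, meta2 <- makeMeta(30, 4L))
  s3 <- makeSplits(meta2, trainConfig(seed = 3))
  expect_length(intersect(meta2$subject_id[s3$train],
                          meta2$subject_id[s3$test]), 0)
})

test_that("the same seed yields identical splits across wavelength views", {
  withr::with_seed(3, meta <- makeMeta(40, 2L))
  tcfg <- trainConfig(seed = 11)
  views <- lapply(1:4, function(k) makeSplits(meta, tcfg))
  for (k in 2:4) expect_identical(views[[k]], views[[1]])
})

test_that("different seeds move the partition", {
  withr::with_seed(4, meta <- makeMeta(50, 1L))
  s1 <- makeSplits(meta, trainConfig(seed = 1))
  s2 <- makeSplits(meta, trainConfig(seed = 2))
  expect_false(identical(s1$test, s2$test))
})

test_that("record-level splitting refuses fewer subjects than folds", {
  withr::with_seed(5, meta <- makeMeta(5, 2L))
  expect_error(makeSplits(meta, trainConfig(cv_folds = 10)), "split error")
})

test_that("window-level splitting is available and seeded", {
  withr::with_seed(6, meta <- makeMeta(10, 6L))
  tcfg <- trainConfig(split_level = "window", cv_folds = 5, seed = 9)
  s <- makeSplits(meta, tcfg)
  expect_equal(length(s$test), 12L)
  expect_identical(s, makeSplits(meta, tcfg))
})

test_that("a tiny smoke run returns fold metrics and a test report", {
  cfg <- tinySimConfig(n = 12, duration = 15, seed = 31)
  co <- simulateCohort(cfg)
  ds <- buildTrialDataset(co, imgSize = 16, stride = 5)
  tcfg <- trainConfig(cv_folds = 2, run_cv = TRUE, epochs = 3,
                      batch_size = 8, seed = 2)
  res <- trainModel(ds, modelConfig(), tcfg)
  expect_equal(nrow(res$foldMetrics), 2L)  # one row per fold
  expect_s4_class(res$report$sbp, "EvalReport")
  expect_s4_class(res$report$dbp, "EvalReport")
  expect_true(res$model@trained)
  expect_length(res$history, 3L)
  expect_equal(nrow(res$predictions),
               length(res$splits$test))
})

test_that("trial orchestration enforces its contracts", {
  cfg <- tinySimConfig(n = 6, duration = 10, seed = 17)
  co <- simulateCohort(cfg)
  ds <- buildTrialDataset(co, imgSize = 16, stride = 5)
  expect_error(runTrial(1, co, dataset = ds), "requires a wavelength")
  expect_error(runTrial(4, co, dataset = ds), "trial must be")

  tcfg <- trainConfig(cv_folds = 2, epochs = 2, batch_size = 8, seed = 5)
  r1 <- runTrial(1, co, channel = 4, dataset = ds, tcfg = tcfg)
  expect_equal(r1$model@config$variant, "single")
  expect_equal(r1$channel, 4)
  r2 <- runTrial(2, co, dataset = ds, tcfg = tcfg)
  expect_equal(r2$model@config$variant, "four_branch")
  r3 <- runTrial(3, co, dataset = ds, tcfg = tcfg)
  expect_equal(r3$model@config$variant, "fused12")

  # identical partitions across the three trials at the same seed
  expect_identical(r1$splits$test, r3$splits$test)
  expect_identical(r2$splits$test, r3$splits$test)
})

test_that("trial 1 trains on exactly one wavelength's image block", {
  cfg <- tinySimConfig(n = 6, duration = 10, seed = 19)
  co <- simulateCohort(cfg)
  ds <- buildTrialDataset(co, imgSize = 16, stride = 5)
  # corrupt channels 1-3; channel 4 intact: a channel-4 model must be
  # unaffected by the corruption
  dsBad <- ds
  dsBad$X[, , , 1:9] <- 0
  tcfg <- trainConfig(cv_folds = 2, epochs = 2, batch_size = 8, seed = 5)
  r4 <- runTrial(1, co, channel = 4, dataset = ds, tcfg = tcfg)
  r4b <- runTrial(1, co, channel = 4, dataset = dsBad, tcfg = tcfg)
  expect_equal(r4$report$sbp@mae, r4b$report$sbp@mae)
})

test_that("the mean-predictor baseline is computed from training labels", {
  expect_equal(meanPredictorBaseline(c(100, 140), c(110, 130)), 10)
})
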