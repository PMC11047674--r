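test_that("metric identities hold on hand-computable cases", {
  # perfect prediction
  r <- computeMetrics(c(120, 110, 130), c(120, 110, 130))
  expect_equal(c(r@me, r@sd, r@mae, r@rmse), c(0, 0, 0, 0))
  expect_equal(r@r2, 1)

  # constant offset
  r <- computeMetrics(c(100, 110, 120), c(102, 112, 122))
  expect_equal(c(r@me, r@mae, r@sd, r@rmse), c(2, 2, 0, 2))

  # errors (+1, -1, +3, -3): ME 0, MAE 2, RMSE sqrt(5), SD sqrt(5)
  yt <- c(100, 110, 120, 130)
  r <- computeMetrics(yt, yt + c(1, -1, 3, -3))
  expect_equal(r@me, 0)
  expect_equal(r@mae, 2)
  expect_equal(r@rmse, sqrt(5))
  expect_equal(r@sd, sqrt(5))
})

test_that("RMSE^2 = ME^2 + SD^2 and MAE <= RMSE for arbitrary errors", {
  withr::with_seed(10, {
    for (i in 1:25) {
      n <- sample(2:60, 1)
      yt <- rnorm(n, 120, 15)
      yp <- yt + rnorm(n, sample(-4:4, 1), runif(1, 0.1, 10))
      r <- computeMetrics(yt, yp)
      expect_lt(abs(r@rmse^2 - (r@me^2 + r@sd^2)), 1e-6)
      expect_lte(r@mae, r@rmse + 1e-12)
      expect_true(!is.unsorted(r@bhsPercentages))
      expect_identical(r@aamiPass, aamiCheck(r@me, r@sd))
    }
  })
})

test_that("input contracts are enforced", {
  expect_error(computeMetrics(1, 1), "sample-size error")
  expect_error(computeMetrics(1:3, 1:4), "equal length")
  expect_error(blandAltman(120, 118), "sample-size error")
  expect_error(bhsGrade(numeric(0)), "sample-size error")
})

test_that("the AAMI verdict uses strict bounds", {
  expect_true(aamiCheck(0.90, 7.66))
  expect_false(aamiCheck(0.58, 8.72))
  expect_false(aamiCheck(5.0, 7.0))   # |ME| boundary is exclusive
  expect_false(aamiCheck(0.0, 8.0))   # SD boundary is exclusive
  expect_true(aamiCheck(-4.99, 7.99))
})

test_that("BHS grading matches the published threshold table", {
  expect_equal(bhsGrade(c(94, 96, 97), percentages = TRUE)$grade, "A")
  expect_equal(bhsGrade(c(60, 85, 95), percentages = TRUE)$grade, "A")
  expect_equal(bhsGrade(c(59, 85, 95), percentages = TRUE)$grade, "B")
  expect_equal(bhsGrade(c(50, 75, 90), percentages = TRUE)$grade, "B")
  expect_equal(bhsGrade(c(40, 65, 85), percentages = TRUE)$grade, "C")
  expect_equal(bhsGrade(c(39, 65, 85), percentages = TRUE)$grade, "D")

  g <- bhsGrade(c(1, 6, 12, 20))
  expect_equal(g$percentages, c(25, 50, 75))
  expect_equal(g$grade, "D")
})

test_that("BHS grading is monotone: adding a zero error never lowers it", {
  withr::with_seed(11, {
    for (i in 1:20) {
      errs <- abs(rnorm(sample(3:40, 1), 0, 8))
      g1 <- bhsGrade(errs)$grade
      g2 <- bhsGrade(c(errs, 0))$grade
      expect_lte(match(g2, c("A", "B", "C", "D")),
                 match(g1, c("A", "B", "C", "D")))
    }
  })
})

test_that("Bland-Altman limits reproduce hand-computed intervals", {
  expect_equal(unname(blandAltmanLimits(0.711, 2.43)),
               c(-4.0518, 5.4738), tolerance = 1e-12)

  yt <- c(100, 120, 140, 110)
  ba <- blandAltman(yt, yt)  # all differences zero
  expect_equal(c(ba$mean_diff, ba$loa_low, ba$loa_high), c(0, 0, 0))
  expect_equal(ba$points$diff, rep(0, 4))

  withr::with_seed(12, {
    yt <- rnorm(40, 120, 12)
    yp <- yt + rnorm(40, 1, 4)
  })
  ba <- blandAltman(yt, yp)
  r <- computeMetrics(yt, yp)
  expect_equal(ba$mean_diff, r@me)
  expect_equal(ba$loa_low, r@me - 1.96 * r@sd)
  expect_equal(ba$loa_high, r@me + 1.96 * r@sd)
})

test_that("reports render to JSON that round-trips, a plot and a table", {
  withr::with_seed(13, {
    yt <- rnorm(30, 120, 10)
    yp <- yt + rnorm(30, 0.5, 3)
  })
  report <- computeMetrics(yt, yp)
  dir <- withr::local_tempdir()
  paths <- renderReport(report, dir, prefix = "sbp")
  expect_true(all(file.exists(paths)))
  expect_gt(file.size(paths["plot"]), 0)

  j <- jsonlite::fromJSON(paths[["json"]])
  expect_equal(j$me, report@me)
  expect_equal(j$sd, report@sd)
  expect_equal(j$mae, report@mae)
  expect_equal(j$rmse, report@rmse)
  expect_equal(j$r2, report@r2)
  expect_equal(j$aami_pass, report@aamiPass)
  expect_equal(j$bhs$grade, report@bhsGrade)
  expect_equal(j$bland_altman$loa_low, report@baLoA[1])

  # table lists the observed percentages next to the grade boundaries
  tbl <- readLines(paths[["table"]])
  expect_true(any(grepl("grade A requires\\s+60\\s+85\\s+95", tbl)))
  expect_true(any(grepl("grade C requires\\s+40\\s+65\\s+85", tbl)))
})

test_that("the training loss equals the evaluation MAE on a batch", {
  withr::with_seed(14, {
    yt <- rnorm(50, 120, 10)
    yp <- yt + rnorm(50, 0, 5)
  })
  expect_lt(abs(maeLoss(yt, yp) - computeMetrics(yt, yp)@mae), 1e-6)
})
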