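#' Regression and device-validation metrics for BP predictions
#'
#' Computes the five regression indexes plus the AAMI verdict, BHS grading
#' and Bland-Altman agreement for one target (SBP or DBP):
#' \itemize{
#'   \item ME, mean error `mean(pred - true)`;
#'   \item SD, the population standard deviation of the errors (divide by
#'     n), so that `RMSE^2 = ME^2 + SD^2` holds exactly;
#'   \item MAE, `mean(|pred - true|)`;
#'   \item RMSE, `sqrt(mean((pred - true)^2))`;
#'   \item R^2, `1 - SSE / SST` with SST about the mean of the reference
#'     values.
#' }
#'
#' @param yTrue,yPred reference and predicted pressures in mmHg, equal
#'   length, n >= 2.
#' @return an [EvalReport-class].
#' @examples
#' computeMetrics(c(120, 130, 110, 140), c(121, 129, 113, 137))
#' @export
computeMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("input error: yTrue and yPred must have equal length")
  n <- length(yTrue)
  if (n < 2L) stop("sample-size error: need at least 2 observations")
  err <- yPred - yTrue
  me <- mean(err)
  sdPop <- sqrt(mean((err - me)^2))
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  sst <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
  bhs <- bhsGrade(abs(err))
  ba <- blandAltman(yTrue, yPred)
  new("EvalReport",
      n = as.integer(n), me = me, sd = sdPop, mae = mae, rmse = rmse,
      r2 = r2,
      aamiPass = aamiCheck(me, sdPop),
      bhsPercentages = bhs$percentages, bhsGrade = bhs$grade,
      baMeanDiff = ba$mean_diff,
      baLoA = c(ba$loa_low, ba$loa_high),
      yTrue = as.numeric(yTrue), yPred = as.numeric(yPred))
}

#' AAMI accuracy criterion
#'
#' Pass requires a mean error strictly below 5 mmHg in magnitude and an
#' error standard deviation strictly below 8 mmHg.
#'
#' @param me mean error, mmHg.
#' @param sd standard deviation of the errors, mmHg.
#' @return logical verdict.
#' @examples
#' aamiCheck(0.90, 7.66)  # TRUE
#' aamiCheck(0.58, 8.72)  # FALSE
#' @export
aamiCheck <- function(me, sd) {
  stopifnot(is.finite(me), is.finite(sd))
  abs(me) < 5 && sd < 8
}

BHS_THRESHOLDS <- rbind(A = c(60, 85, 95), B = c(50, 75, 90),
                        C = c(40, 65, 85))

#' BHS cumulative-error grading
#'
#' Computes the cumulative percentages of absolute errors within 5, 10 and
#' 15 mmHg and assigns the best grade whose three thresholds are all met
#' (A: 60/85/95, B: 50/75/90, C: 40/65/85, inclusive), or D otherwise.
#'
#' @param absErrors absolute errors in mmHg (non-empty), or a length-3
#'   vector of cumulative percentages via `percentages = TRUE`.
#' @param percentages set to `TRUE` when passing pre-computed cumulative
#'   percentages instead of raw errors.
#' @return list with `percentages` (length 3) and `grade`.
#' @examples
#' bhsGrade(c(1, 6, 12, 20))              # 25/50/75 -> "D"
#' bhsGrade(c(94, 96, 97), percentages = TRUE)  # "A"
#' @export
bhsGrade <- function(absErrors, percentages = FALSE) {
  if (percentages) {
    pct <- as.numeric(absErrors)
    if (length(pct) != 3L)
      stop("expected three cumulative percentages (<=5, <=10, <=15 mmHg)")
  } else {
    if (length(absErrors) == 0L)
      stop("sample-size error: no errors supplied")
    absErrors <- abs(absErrors)
    pct <- 100 * vapply(c(5, 10, 15), function(th)
      mean(absErrors <= th), numeric(1))
  }
  grade <- "D"
  for (g in c("C", "B", "A"))
    if (all(pct >= BHS_THRESHOLDS[g, ])) grade <- g
  list(percentages = pct, grade = grade)
}

#' Bland-Altman limits of agreement from summary statistics
#'
#' @param me mean difference (predicted minus reference), mmHg.
#' @param sd standard deviation of the differences, mmHg.
#' @return numeric vector `c(loa_low, loa_high) = me -/+ 1.96 * sd`.
#' @examples
#' blandAltmanLimits(0.711, 2.43)  # -4.052, 5.474
#' @export
blandAltmanLimits <- function(me, sd) {
  c(loa_low = me - 1.96 * sd, loa_high = me + 1.96 * sd)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference and 95% limits of agreement (`ME +/- 1.96 SD` with the
#' population SD of the differences), plus the per-point table used for the
#' agreement plot.
#'
#' @param yTrue,yPred reference and predicted pressures, mmHg, n >= 2.
#' @return list with `mean_diff`, `loa_low`, `loa_high` and `points`, a
#'   data frame of pair means and differences.
#' @export
blandAltman <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("input error: yTrue and yPred must have equal length")
  if (length(yTrue) < 2L)
    stop("sample-size error: need at least 2 observations")
  diffs <- yPred - yTrue
  md <- mean(diffs)
  s <- sqrt(mean((diffs - md)^2))
  loa <- blandAltmanLimits(md, s)
  list(mean_diff = md, loa_low = unname(loa[1]), loa_high = unname(loa[2]),
       points = data.frame(mean = (yTrue + yPred) / 2, diff = diffs))
}

reportToList <- function(report) {
  list(n = report@n, me = report@me, sd = report@sd, mae = report@mae,
       rmse = report@rmse, r2 = report@r2, aami_pass = report@aamiPass,
       bhs = list(pct_le_5 = report@bhsPercentages[1],
                  pct_le_10 = report@bhsPercentages[2],
                  pct_le_15 = report@bhsPercentages[3],
                  grade = report@bhsGrade,
                  grade_thresholds = list(A = BHS_THRESHOLDS["A", ],
                                          B = BHS_THRESHOLDS["B", ],
                                          C = BHS_THRESHOLDS["C", ])),
       bland_altman = list(mean_diff = report@baMeanDiff,
                           loa_low = report@baLoA[1],
                           loa_high = report@baLoA[2]))
}

#' Render an evaluation report to disk
#'
#' Writes a versioned JSON metrics file, a Bland-Altman plot with the mean
#' and limit lines, and a plain-text AAMI/BHS summary table listing the
#' observed cumulative percentages alongside the grade boundaries.
#'
#' @param report an [EvalReport-class].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, e.g. `"sbp"`.
#' @return (invisibly) the paths written.
#' @export
renderReport <- function(report, dir, prefix = "bp") {
  stopifnot(is(report, "EvalReport"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", dir)
  jsonPath <- file.path(dir, paste0(prefix, "_metrics.json"))
  payload <- c(list(schema = "mwppg-eval-report/1"), reportToList(report))
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA)

  plotPath <- file.path(dir, paste0(prefix, "_bland_altman.png"))
  grDevices::png(plotPath, width = 800, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  pts <- data.frame(mean = (report@yTrue + report@yPred) / 2,
                    diff = report@yPred - report@yTrue)
  graphics::plot(pts$mean, pts$diff,
                 xlab = "Mean of prediction and reference (mmHg)",
                 ylab = "Prediction - reference (mmHg)",
                 main = sprintf("Bland-Altman (%s)", prefix),
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.6),
                 ylim = range(c(pts$diff, report@baLoA)) + c(-1, 1))
  graphics::abline(h = report@baMeanDiff, lty = 2)
  graphics::abline(h = report@baLoA, lty = 3, col = "red3")

  tablePath <- file.path(dir, paste0(prefix, "_summary.txt"))
  pct <- report@bhsPercentages
  lines <- c(
    sprintf("n = %d", report@n),
    sprintf("ME %+.3f  SD %.3f  MAE %.3f  RMSE %.3f mmHg  R^2 %.3f",
            report@me, report@sd, report@mae, report@rmse, report@r2),
    sprintf("AAMI (|ME| < 5, SD < 8 mmHg): %s",
            if (report@aamiPass) "pass" else "fail"),
    "",
    "BHS cumulative percentages   <=5    <=10   <=15   grade",
    sprintf("  observed                   %5.1f  %5.1f  %5.1f   %s",
            pct[1], pct[2], pct[3], report@bhsGrade),
    sprintf("  grade A requires           %5.0f  %5.0f  %5.0f",
            BHS_THRESHOLDS["A", 1], BHS_THRESHOLDS["A", 2],
            BHS_THRESHOLDS["A", 3]),
    sprintf("  grade B requires           %5.0f  %5.0f  %5.0f",
            BHS_THRESHOLDS["B", 1], BHS_THRESHOLDS["B", 2],
            BHS_THRESHOLDS["B", 3]),
    sprintf("  grade C requires           %5.0f  %5.0f  %5.0f",
            BHS_THRESHOLDS["C", 1], BHS_THRESHOLDS["C", 2],
            BHS_THRESHOLDS["C", 3]))
  writeLines(lines, tablePath)
  invisible(c(json = jsonPath, plot = plotPath, table = tablePath))
}
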