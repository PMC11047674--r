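#' @import methods
NULL

WAVELENGTHS_NM <- c(660L, 730L, 850L, 940L)

#' MWPPGRecord: one subject's four-wavelength PPG recording
#'
#' Container for a single acquisition: four simultaneously sampled PPG
#' channels (660, 730, 850 and 940 nm, in that fixed order) plus optional
#' cuff reference blood-pressure labels in mmHg.
#'
#' @slot subjectId character scalar identifier.
#' @slot samples numeric matrix, one column per wavelength channel
#'   (Channel 1 = 660 nm ... Channel 4 = 940 nm), one row per sample.
#' @slot fs sampling rate in Hz.
#' @slot wavelengths integer vector of the four LED wavelengths in nm.
#' @slot sbp,dbp reference systolic/diastolic pressure in mmHg (`NA` when
#'   the record is unlabeled).
#' @slot hypertensive logical; `TRUE` when SBP >= 130 or DBP >= 90 mmHg.
#' @exportClass MWPPGRecord
setClass("MWPPGRecord",
  representation(
    subjectId = "character",
    samples = "matrix",
    fs = "numeric",
    wavelengths = "integer",
    sbp = "numeric",
    dbp = "numeric",
    hypertensive = "logical"
  ),
  prototype(
    subjectId = "unknown", fs = 200,
    wavelengths = WAVELENGTHS_NM,
    sbp = NA_real_, dbp = NA_real_, hypertensive = NA
  )
)

setValidity("MWPPGRecord", function(object) {
  msg <- character()
  if (ncol(object@samples) != 4L)
    msg <- c(msg, "samples must have exactly 4 channels (columns)")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!identical(object@wavelengths, WAVELENGTHS_NM))
    msg <- c(msg, "wavelengths must be 660, 730, 850, 940 nm in that order")
  if (is.finite(object@sbp) && is.finite(object@dbp) &&
      object@sbp <= object@dbp)
    msg <- c(msg, "sbp must exceed dbp")
  if (length(msg)) msg else TRUE
})

#' WindowSet: aligned 5-second windows cut from one record
#'
#' Windows are cut simultaneously across the four wavelength channels so
#' that window i covers identical sample indices in every channel. Each
#' window inherits the record's cuff (SBP, DBP) label.
#'
#' @slot windows numeric array `winLen x nWindows x 4`.
#' @slot subjectId character scalar.
#' @slot windowIndex integer vector of original window positions (1-based).
#' @slot fs sampling rate in Hz.
#' @slot sbp,dbp inherited labels in mmHg.
#' @exportClass WindowSet
setClass("WindowSet",
  representation(
    windows = "array",
    subjectId = "character",
    windowIndex = "integer",
    fs = "numeric",
    sbp = "numeric",
    dbp = "numeric"
  )
)

setValidity("WindowSet", function(object) {
  d <- dim(object@windows)
  msg <- character()
  if (length(d) != 3L || d[3] != 4L)
    msg <- c(msg, "windows must be a winLen x nWindows x 4 array")
  if (length(object@windowIndex) != d[2])
    msg <- c(msg, "windowIndex length must equal the number of windows")
  if (length(msg)) msg else TRUE
})

#' Scalogram: CWT magnitude over scale and time
#'
#' @slot magnitudes non-negative numeric matrix, scales in rows (ordered by
#'   increasing scale, i.e. decreasing pseudo-frequency), time in columns.
#' @slot scales positive numeric vector of scale values, in samples.
#' @slot wavelet character name of the wavelet basis (`"cgau1"`).
#' @slot fs sampling rate of the analysed window, in Hz.
#' @exportClass Scalogram
setClass("Scalogram",
  representation(
    magnitudes = "matrix",
    scales = "numeric",
    wavelet = "character",
    fs = "numeric"
  )
)

setValidity("Scalogram", function(object) {
  msg <- character()
  if (nrow(object@magnitudes) != length(object@scales))
    msg <- c(msg, "one row of magnitudes per scale required")
  if (any(object@magnitudes < 0))
    msg <- c(msg, "magnitudes must be non-negative")
  if (any(object@scales <= 0))
    msg <- c(msg, "scales must be positive")
  if (is.unsorted(object@scales, strictly = TRUE))
    msg <- c(msg, "scales must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' FusedTensor: depth-stacked RGB scalograms of the four channels
#'
#' The four per-wavelength RGB scalogram images are stacked along depth into
#' a single `H x W x 12` array. Depth blocks `1:3`, `4:6`, `7:9`, `10:12`
#' hold Channels 1 to 4 respectively; the block order is fixed.
#'
#' @slot pixels numeric array `H x W x 12`, values in `[0, 1]`.
#' @exportClass FusedTensor
setClass("FusedTensor", representation(pixels = "array"))

setValidity("FusedTensor", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 3L || d[3] != 12L)
    msg <- c(msg, "pixels must be an H x W x 12 array")
  if (any(object@pixels < 0 | object@pixels > 1))
    msg <- c(msg, "pixel values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EvalReport: regression and device-validation metrics
#'
#' Holds the standard regression metrics (ME, SD, MAE, RMSE, R^2), the AAMI
#' verdict (|ME| < 5 mmHg and SD < 8 mmHg), BHS cumulative error percentages
#' with the resulting grade, and Bland-Altman limits of agreement. SD is the
#' population standard deviation of the errors, so RMSE^2 = ME^2 + SD^2
#' holds exactly.
#'
#' @slot n sample count.
#' @slot me,sd,mae,rmse error statistics in mmHg.
#' @slot r2 coefficient of determination.
#' @slot aamiPass logical AAMI verdict.
#' @slot bhsPercentages cumulative percentages of absolute errors
#'   <= 5, 10, 15 mmHg.
#' @slot bhsGrade character grade "A", "B", "C" or "D".
#' @slot baMeanDiff Bland-Altman mean difference (equals ME), mmHg.
#' @slot baLoA lower and upper 95% limits of agreement, mmHg.
#' @slot yTrue,yPred the underlying reference and predicted values, kept so
#'   reports can be re-rendered (Bland-Altman scatter) without the model.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    n = "integer",
    me = "numeric", sd = "numeric", mae = "numeric", rmse = "numeric",
    r2 = "numeric",
    aamiPass = "logical",
    bhsPercentages = "numeric",
    bhsGrade = "character",
    baMeanDiff = "numeric",
    baLoA = "numeric",
    yTrue = "numeric", yPred = "numeric"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (length(object@bhsPercentages) != 3L)
    msg <- c(msg, "bhsPercentages must have 3 entries (<=5, <=10, <=15 mmHg)")
  if (is.unsorted(object@bhsPercentages))
    msg <- c(msg, "bhsPercentages must be non-decreasing in the threshold")
  if (!object@bhsGrade %in% c("A", "B", "C", "D"))
    msg <- c(msg, "bhsGrade must be one of A, B, C, D")
  if (length(msg)) msg else TRUE
})

#' BPModel: attention CNN + bidirectional LSTM blood-pressure regressor
#'
#' Wraps the network parameters together with the architecture configuration
#' and the label standardisation learned at training time. Predictions are
#' produced in mmHg via [predictBP()].
#'
#' @slot config the `mwppgModelConfig` list used to build the network.
#' @slot params named list of parameter arrays (conv kernels, batch-norm
#'   statistics, attention bottlenecks, LSTM and dense weights).
#' @slot labelCenter,labelScale per-output standardisation (SBP, DBP) learned
#'   from the training labels; identity until the model is fitted.
#' @slot trained logical.
#' @exportClass BPModel
setOldClass("mwppgModelConfig")

setClass("BPModel",
  representation(
    config = "mwppgModelConfig",
    params = "list",
    labelCenter = "numeric",
    labelScale = "numeric",
    trained = "logical"
  ),
  prototype(labelCenter = c(0, 0), labelScale = c(1, 1), trained = FALSE)
)
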