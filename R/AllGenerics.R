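#' Accessors for mwppg classes
#'
#' Small accessor generics so user code never reaches into slots directly.
#'
#' @param x an mwppg object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ppgSamples", function(x, ...) standardGeneric("ppgSamples"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x, ...) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x, ...) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("bpLabels", function(x, ...) standardGeneric("bpLabels"))

#' @rdname accessors
#' @export
setGeneric("magnitudes", function(x, ...) standardGeneric("magnitudes"))

#' @rdname accessors
#' @export
setGeneric("cwtScales", function(x, ...) standardGeneric("cwtScales"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x, ...) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("nWindows", function(x, ...) standardGeneric("nWindows"))

#' @rdname accessors
setMethod("ppgSamples", "MWPPGRecord", function(x, ...) x@samples)

#' @rdname accessors
setMethod("ppgSamples", "WindowSet", function(x, ...) x@windows)

#' @rdname accessors
setMethod("sampleRate", "MWPPGRecord", function(x, ...) x@fs)

#' @rdname accessors
setMethod("sampleRate", "WindowSet", function(x, ...) x@fs)

#' @rdname accessors
setMethod("sampleRate", "Scalogram", function(x, ...) x@fs)

#' @rdname accessors
setMethod("subjectId", "MWPPGRecord", function(x, ...) x@subjectId)

#' @rdname accessors
setMethod("subjectId", "WindowSet", function(x, ...) x@subjectId)

#' @rdname accessors
setMethod("bpLabels", "MWPPGRecord", function(x, ...)
  c(sbp = x@sbp, dbp = x@dbp))

#' @rdname accessors
setMethod("bpLabels", "WindowSet", function(x, ...)
  c(sbp = x@sbp, dbp = x@dbp))

#' @rdname accessors
setMethod("magnitudes", "Scalogram", function(x, ...) x@magnitudes)

#' @rdname accessors
setMethod("cwtScales", "Scalogram", function(x, ...) x@scales)

#' @rdname accessors
setMethod("pixels", "FusedTensor", function(x, ...) x@pixels)

#' @rdname accessors
setMethod("nWindows", "WindowSet", function(x, ...) dim(x@windows)[2])

#' Extract one wavelength's RGB block from a fused tensor
#'
#' @param x a [FusedTensor-class].
#' @param channel channel number 1-4 (660, 730, 850, 940 nm).
#' @return the `H x W x 3` RGB image of that wavelength, exactly as fused.
#' @export
channelBlock <- function(x, channel) {
  stopifnot(is(x, "FusedTensor"))
  if (!channel %in% 1:4) stop("channel must be 1, 2, 3 or 4")
  x@pixels[, , (3L * (channel - 1L) + 1L):(3L * channel), drop = FALSE]
}

setMethod("show", "MWPPGRecord", function(object) {
  cat(sprintf(
    "MWPPGRecord '%s': 4 channels x %d samples @ %g Hz (%.1f s)\n",
    object@subjectId, nrow(object@samples), object@fs,
    nrow(object@samples) / object@fs))
  if (is.finite(object@sbp))
    cat(sprintf("  labels: SBP %.0f / DBP %.0f mmHg%s\n", object@sbp,
                object@dbp,
                if (isTRUE(object@hypertensive)) " (hypertensive)" else ""))
  else cat("  labels: none\n")
})

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf(
    "WindowSet '%s': %d aligned windows x 4 channels, %d samples each @ %g Hz\n",
    object@subjectId, d[2], d[1], object@fs))
})

setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram (%s): %d scales x %d time points @ %g Hz\n",
              object@wavelet, nrow(object@magnitudes),
              ncol(object@magnitudes), object@fs))
  pf <- range(pseudoFrequencies(object))
  cat(sprintf("  pseudo-frequencies %.2f-%.2f Hz\n", pf[1], pf[2]))
})

setMethod("show", "FusedTensor", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FusedTensor: %d x %d x 12 (four RGB blocks, Ch1..Ch4)\n",
              d[1], d[2]))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (n = %d)\n", object@n))
  cat(sprintf("  ME %+.2f  SD %.2f  MAE %.2f  RMSE %.2f mmHg   R^2 %.3f\n",
              object@me, object@sd, object@mae, object@rmse, object@r2))
  cat(sprintf("  AAMI (|ME| < 5, SD < 8): %s\n",
              if (object@aamiPass) "pass" else "fail"))
  cat(sprintf("  BHS: %.0f%% <=5, %.0f%% <=10, %.0f%% <=15 mmHg -> grade %s\n",
              object@bhsPercentages[1], object@bhsPercentages[2],
              object@bhsPercentages[3], object@bhsGrade))
  cat(sprintf("  Bland-Altman: %.3f [%.3f, %.3f] mmHg\n",
              object@baMeanDiff, object@baLoA[1], object@baLoA[2]))
})

setMethod("show", "BPModel", function(object) {
  cfg <- object@config
  cat(sprintf("BPModel (%s): %d conv blocks (%s), BiLSTM %dx%d, fc %s\n",
              cfg$variant, cfg$convBlocks,
              paste(cfg$convChannels, collapse = "-"),
              cfg$lstmLayers, cfg$lstmHidden,
              paste(cfg$fcSizes, collapse = "-")))
  cat(sprintf("  %d trainable parameters; %s\n", countParameters(object),
              if (object@trained) "trained" else "untrained"))
})
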