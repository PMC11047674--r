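#' Training protocol configuration
#'
#' Mirrors the study protocol: Adam optimiser at learning rate 0.001, mean
#' absolute error loss, an 0.8/0.2 train/test partition and 10-fold
#' cross-validation over the training portion. Epoch count and batch size
#' are owned by this configuration.
#'
#' `split_level = "record"` (the default) keeps every window of a subject
#' on the same side of every partition, so the held-out metrics are
#' subject-disjoint; `"window"` splits individual windows, which leaks
#' heavily-overlapping windows of one subject across the split and is kept
#' only for protocol comparison.
#'
#' @param learning_rate Adam learning rate.
#' @param split training fraction of the 80/20 partition.
#' @param cv_folds number of cross-validation folds over the training
#'   portion (>= 2).
#' @param run_cv whether [trainModel()] actually runs the fold loop; the
#'   held-out test evaluation is produced either way, so the default skips
#'   the (purely diagnostic) fold loop to keep desk-scale runs fast.
#' @param epochs,batch_size optimisation schedule.
#' @param seed seed controlling the partition, fold assignment, weight
#'   initialisation and batch shuffling.
#' @param split_level `"record"` or `"window"`.
#' @return a validated list of class `mwppgTrainConfig`.
#' @export
trainConfig <- function(learning_rate = 0.001, split = 0.8, cv_folds = 10L,
                        run_cv = FALSE, epochs = 40L, batch_size = 32L,
                        seed = 1L, split_level = c("record", "window")) {
  split_level <- match.arg(split_level)
  cfg <- list(optimizer = "adam", loss = "mae",
              learning_rate = learning_rate, split = split,
              cv_folds = as.integer(cv_folds), run_cv = isTRUE(run_cv),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              seed = as.integer(seed), split_level = split_level)
  if (split <= 0 || split >= 1) stop("split must lie strictly in (0, 1)")
  if (cfg$cv_folds < 2L) stop("cv_folds must be >= 2")
  if (cfg$epochs < 1L || cfg$batch_size < 1L)
    stop("epochs and batch_size must be >= 1")
  class(cfg) <- "mwppgTrainConfig"
  cfg
}

#' Deterministic train/test partition and cross-validation folds
#'
#' Produces the 80/20 partition and the fold assignment over the training
#' portion. The partition depends only on the subject ids (or window count)
#' and the seed, so the four per-wavelength views of the same cohort
#' receive identical index sets. At `split_level = "record"` all windows of
#' a subject land on the same side.
#'
#' @param meta data frame with one row per sample and a `subject_id`
#'   column (as produced by [buildTrialDataset()]).
#' @param tcfg an `mwppgTrainConfig`.
#' @return list with `train`, `test` (row indices into `meta`), `foldOf`
#'   (fold id per training row) and the subject-level assignments.
#' @export
makeSplits <- function(meta, tcfg = trainConfig()) {
  if (nrow(meta) == 0L) stop("empty dataset")
  if (tcfg$split_level == "record") {
    subjects <- sort(unique(meta$subject_id))
    if (length(subjects) < tcfg$cv_folds)
      stop("split error: fewer records than folds at record level")
    withr::with_seed(tcfg$seed, {
      ord <- sample(subjects)
      nTest <- max(1L, round((1 - tcfg$split) * length(subjects)))
      testSubjects <- sort(ord[seq_len(nTest)])
      trainSubjects <- sort(setdiff(subjects, testSubjects))
      foldOfSubject <- stats::setNames(
        rep_len(seq_len(tcfg$cv_folds), length(trainSubjects)),
        sample(trainSubjects))
    })
    train <- which(meta$subject_id %in% trainSubjects)
    test <- which(meta$subject_id %in% testSubjects)
    foldOf <- unname(foldOfSubject[meta$subject_id[train]])
    list(train = train, test = test, foldOf = foldOf,
         trainSubjects = trainSubjects, testSubjects = testSubjects)
  } else {
    n <- nrow(meta)
    if (n < tcfg$cv_folds) stop("split error: fewer windows than folds")
    withr::with_seed(tcfg$seed, {
      ord <- sample.int(n)
      nTest <- max(1L, round((1 - tcfg$split) * n))
      test <- sort(ord[seq_len(nTest)])
      train <- sort(setdiff(seq_len(n), test))
      foldOf <- sample(rep_len(seq_len(tcfg$cv_folds), length(train)))
    })
    list(train = train, test = test, foldOf = foldOf,
         trainSubjects = unique(meta$subject_id[train]),
         testSubjects = unique(meta$subject_id[test]))
  }
}

#' Build the fused image dataset for a cohort
#'
#' Runs every record through the preprocessing pipeline (band-pass filter,
#' per-record z-score, simultaneous windowing, abnormal-segment rejection),
#' converts each retained window of each wavelength into a CWT scalogram
#' RGB image, and fuses the four images into a 12-channel tensor.
#'
#' @param cohort list with `records` as produced by [simulateCohort()], or
#'   a plain list of labelled [MWPPGRecord-class] objects.
#' @param imgSize image side in pixels (square images).
#' @param win,stride window length and hop in seconds. The default hop of
#'   3 s (19 windows per 60 s record) is the desk-scale training
#'   condition; pass `stride = 1` for the dense 56-window cut.
#' @param rule quality rule for [rejectAbnormal()], or `NULL` to skip.
#' @param scales CWT scale grid; defaults to [defaultScales()].
#' @return list with `X` (array `H x W x N x 12`), `meta` (data frame
#'   `subject_id`, `window`, `sbp`, `dbp`) and `dropLog`.
#' @export
buildTrialDataset <- function(cohort, imgSize = 32, win = 5, stride = 3,
                              rule = qualityRule(), scales = NULL) {
  records <- if (!is.null(cohort$records)) cohort$records else cohort
  stopifnot(length(records) >= 1L)
  fs <- sampleRate(records[[1]])
  if (is.null(scales)) scales <- defaultScales(fs)
  tensors <- list(); metas <- list(); logs <- list()
  for (rec in records) {
    ws <- preprocessRecord(rec, win = win, stride = stride)
    if (!is.null(rule)) {
      rj <- rejectAbnormal(ws, rule)
      ws <- rj$windows
      if (nrow(rj$dropLog)) logs[[length(logs) + 1L]] <- rj$dropLog
    }
    nw <- nWindows(ws)
    if (nw == 0L) next
    for (w in seq_len(nw)) {
      imgs <- lapply(1:4, function(k)
        scalogramToRGB(cwtScalogram(ws@windows[, w, k], fs, scales),
                       size = c(imgSize, imgSize)))
      tensors[[length(tensors) + 1L]] <- pixels(fuseChannels(imgs))
      metas[[length(metas) + 1L]] <- data.frame(
        subject_id = ws@subjectId, window = ws@windowIndex[w],
        sbp = ws@sbp, dbp = ws@dbp, stringsAsFactors = FALSE)
    }
  }
  if (!length(tensors)) stop("no windows survived preprocessing")
  X <- array(unlist(tensors),
             dim = c(imgSize, imgSize, 12L, length(tensors)))
  X <- aperm(X, c(1, 2, 4, 3))  # (H, W, N, C)
  list(X = X, meta = do.call(rbind, metas),
       dropLog = if (length(logs)) do.call(rbind, logs) else NULL)
}

evalPredictions <- function(model, X, meta, idx) {
  preds <- predictBP(model, X[, , idx, , drop = FALSE])
  list(sbp = computeMetrics(meta$sbp[idx], preds[, "sbp"]),
       dbp = computeMetrics(meta$dbp[idx], preds[, "dbp"]),
       predictions = data.frame(subject_id = meta$subject_id[idx],
                                window = meta$window[idx],
                                sbp_hat = preds[, "sbp"],
                                dbp_hat = preds[, "dbp"]))
}

#' Train the regressor under the study protocol
#'
#' Partitions the dataset 80/20, optionally runs the k-fold
#' cross-validation loop over the training portion (`tcfg$run_cv`), refits
#' on the full training portion, and evaluates once on the untouched 20%.
#'
#' @param dataset a list from [buildTrialDataset()] (fields `X`, `meta`),
#'   possibly with `X` sliced to 3 channels for single-wavelength models.
#' @param mcfg an `mwppgModelConfig`.
#' @param tcfg an `mwppgTrainConfig`.
#' @param verbose print per-epoch loss.
#' @return list with `model` (trained [BPModel-class]), `foldMetrics`
#'   (data frame, one row per fold; `NULL` when the fold loop is skipped),
#'   `report` (`$sbp`, `$dbp` [EvalReport-class] on the held-out test set),
#'   `splits` and `history`.
#' @export
trainModel <- function(dataset, mcfg = modelConfig(), tcfg = trainConfig(),
                       verbose = FALSE) {
  X <- dataset$X; meta <- dataset$meta
  inC <- dim(X)[4]
  splits <- makeSplits(meta, tcfg)
  Y <- as.matrix(meta[, c("sbp", "dbp")])
  imgSize <- dim(X)[1:2]
  foldMetrics <- NULL
  if (tcfg$run_cv) {
    rows <- lapply(sort(unique(splits$foldOf)), function(f) {
      val <- splits$train[splits$foldOf == f]
      trn <- setdiff(splits$train, val)
      m <- buildModel(mcfg, inC, imgSize, seed = tcfg$seed + f)
      fit <- fitNetwork(m, X[, , trn, , drop = FALSE],
                        Y[trn, , drop = FALSE],
                        epochs = tcfg$epochs, batchSize = tcfg$batch_size,
                        lr = tcfg$learning_rate, seed = tcfg$seed + f,
                        verbose = verbose)
      ev <- evalPredictions(fit$model, X, meta, val)
      data.frame(fold = f, n_val = length(val),
                 sbp_mae = ev$sbp@mae, sbp_rmse = ev$sbp@rmse,
                 dbp_mae = ev$dbp@mae, dbp_rmse = ev$dbp@rmse)
    })
    foldMetrics <- do.call(rbind, rows)
  }
  model <- buildModel(mcfg, inC, imgSize, seed = tcfg$seed)
  fit <- fitNetwork(model, X[, , splits$train, , drop = FALSE],
                    Y[splits$train, , drop = FALSE],
                    epochs = tcfg$epochs, batchSize = tcfg$batch_size,
                    lr = tcfg$learning_rate, seed = tcfg$seed,
                    verbose = verbose)
  ev <- evalPredictions(fit$model, X, meta, splits$test)
  list(model = fit$model, foldMetrics = foldMetrics,
       report = list(sbp = ev$sbp, dbp = ev$dbp),
       predictions = ev$predictions, splits = splits,
       history = fit$history)
}

#' Mean-predictor baseline MAE
#'
#' The MAE obtained on the test labels by always predicting the mean of
#' the training labels; the reference against which any learned model must
#' be judged.
#'
#' @param yTrain,yTest training and test labels, mmHg.
#' @return baseline MAE in mmHg.
#' @export
meanPredictorBaseline <- function(yTrain, yTest)
  mean(abs(yTest - mean(yTrain)))

#' Run one of the three fusion trials
#'
#' Trial 1 trains the single-image variant on one wavelength's RGB
#' scalograms; Trial 2 trains the four-branch variant (one weight-
#' independent conv stack per wavelength, features spliced before the
#' recurrent stage); Trial 3 trains the fused 12-channel variant. All
#' trials share the partition produced by `tcfg$seed`, so their held-out
#' sets are identical.
#'
#' @param trial 1, 2 or 3.
#' @param cohort cohort from [simulateCohort()] or list of labelled
#'   records.
#' @param channel wavelength channel 1-4; required for trial 1.
#' @param mcfg model configuration; the variant is forced to match the
#'   trial.
#' @param tcfg training configuration.
#' @param dataset optional pre-built [buildTrialDataset()] result (reused
#'   across trials to avoid recomputing scalograms).
#' @param imgSize,stride dataset settings when `dataset` is not supplied.
#' @param verbose print per-epoch loss.
#' @return as [trainModel()], plus `trial` and `channel`.
#' @export
runTrial <- function(trial, cohort, channel = NULL, mcfg = NULL,
                     tcfg = trainConfig(), dataset = NULL,
                     imgSize = 32, stride = 3, verbose = FALSE) {
  if (!trial %in% 1:3) stop("trial must be 1, 2 or 3")
  if (trial == 1 && is.null(channel))
    stop("configuration error: trial 1 requires a wavelength channel")
  if (is.null(dataset))
    dataset <- buildTrialDataset(cohort, imgSize = imgSize, stride = stride)
  variant <- c("single", "four_branch", "fused12")[trial]
  if (is.null(mcfg)) mcfg <- modelConfig(variant = variant)
  if (mcfg$variant != variant) {
    mcfg$variant <- variant
    class(mcfg) <- "mwppgModelConfig"
  }
  if (trial == 1) {
    cols <- (3L * (channel - 1L) + 1L):(3L * channel)
    dataset <- list(X = dataset$X[, , , cols, drop = FALSE],
                    meta = dataset$meta)
  }
  out <- trainModel(dataset, mcfg, tcfg, verbose = verbose)
  out$trial <- trial
  out$channel <- if (trial == 1) channel else NULL
  out
}
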