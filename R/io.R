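#' Read a four-channel PPG recording from a plain-text file
#'
#' The on-disk dialect is one row per sample time with four numeric columns
#' in Channel 1..4 order (660, 730, 850, 940 nm), whitespace- or
#' comma-delimited. Blank lines and lines starting with `#` are ignored.
#'
#' @param path file to read.
#' @param fs sampling rate in Hz (the file stores no rate).
#' @param subjectId identifier for the returned record; defaults to the file
#'   name without extension.
#' @return an unlabeled [MWPPGRecord-class].
#' @seealso [writeRecord()], [readLabels()]
#' @export
readRecord <- function(path, fs = 200, subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  dataLines <- lines[keep]
  lineNo <- which(keep)
  if (length(dataLines) == 0L) {
    return(new("MWPPGRecord", subjectId = subjectId,
               samples = matrix(numeric(0), 0, 4), fs = fs))
  }
  fields <- strsplit(trimws(dataLines), "[,[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop(sprintf(
      "parse error at line %d of '%s': expected 4 columns, found %d",
      lineNo[bad], path, nf[bad]))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    badRow <- ceiling(which(is.na(vals))[1] / 4)
    stop(sprintf("parse error at line %d of '%s': non-numeric field",
                 lineNo[badRow], path))
  }
  samples <- matrix(vals, ncol = 4, byrow = TRUE)
  new("MWPPGRecord", subjectId = subjectId, samples = samples, fs = fs)
}

#' Write a recording in the plain-text dialect read by [readRecord()]
#'
#' Samples are printed with six decimal places, space-delimited, preceded by
#' comment lines recording the subject id, sampling rate and channel order.
#'
#' @param record an [MWPPGRecord-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRecord <- function(record, path) {
  stopifnot(is(record, "MWPPGRecord"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject: %s", record@subjectId),
    sprintf("# fs_hz: %g", record@fs),
    "# columns: ch1_660nm ch2_730nm ch3_850nm ch4_940nm"
  ), con)
  if (nrow(record@samples) > 0L) {
    writeLines(apply(record@samples, 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a reference blood-pressure labels table
#'
#' Expects a CSV with header `subject_id,sbp,dbp`. A `hypertensive` flag is
#' added using the SBP >= 130 mmHg or DBP >= 90 mmHg rule.
#'
#' @param path CSV file.
#' @return data frame with columns `subject_id`, `sbp`, `dbp`,
#'   `hypertensive`.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sbp", "dbp")
  if (!all(need %in% names(df)))
    stop("labels file must have columns subject_id, sbp, dbp")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in labels: ",
         df$subject_id[duplicated(df$subject_id)][1])
  if (!is.numeric(df$sbp) || !is.numeric(df$dbp))
    stop("sbp and dbp must be numeric")
  bad <- which(df$sbp <= df$dbp)
  if (length(bad))
    stop(sprintf("validation error: sbp <= dbp for subject '%s'",
                 df$subject_id[bad[1]]))
  df$hypertensive <- df$sbp >= 130 | df$dbp >= 90
  df[, c("subject_id", "sbp", "dbp", "hypertensive")]
}

#' Write a labels table in the dialect read by [readLabels()]
#'
#' @param labels data frame with `subject_id`, `sbp`, `dbp`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
  utils::write.csv(labels[, c("subject_id", "sbp", "dbp")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach cuff labels to a record
#'
#' @param record an [MWPPGRecord-class].
#' @param labels a labels data frame as returned by [readLabels()].
#' @return the labelled record.
#' @export
attachLabels <- function(record, labels) {
  i <- match(record@subjectId, labels$subject_id)
  if (is.na(i)) stop("no label row for subject ", record@subjectId)
  record@sbp <- as.numeric(labels$sbp[i])
  record@dbp <- as.numeric(labels$dbp[i])
  record@hypertensive <- record@sbp >= 130 || record@dbp >= 90
  validObject(record)
  record
}

#' One-line sanity summary of a recording file
#'
#' @param path signal file.
#' @param fs assumed sampling rate in Hz.
#' @return (invisibly) a list with `channels`, `samples`, `seconds`.
#' @export
inspectRecord <- function(path, fs = 200) {
  rec <- readRecord(path, fs = fs)
  out <- list(channels = ncol(rec@samples), samples = nrow(rec@samples),
              seconds = nrow(rec@samples) / fs)
  message(sprintf("%s: %d channels x %d samples (%.1f s @ %g Hz)",
                  basename(path), out$channels, out$samples, out$seconds, fs))
  invisible(out)
}
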