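## Trial-table CSV and model JSON persistence. Floats are serialized at
## full (17 significant digit) precision so round trips are bit-exact.

trialTableCols <- c("participant", "trial", "onset_sample", "wt_s", "md_s",
                    "pa", "score", "excluded", "reason")

#' Write / read a trial table
#'
#' The trial table holds one row per trial with the detected movement
#' onset, waiting time (WT, s), movement duration (MD, s), peak
#' acceleration (PA, device units), the integer feedback score, and the
#' exclusion flag plus reason code. Schema:
#' `participant,trial,onset_sample,wt_s,md_s,pa,score,excluded,reason`.
#'
#' @param records Data frame with the columns above.
#' @param path Output CSV path.
#' @return `writeTrialTable`: `path` invisibly. `readTrialTable`: the data
#'   frame, with types restored.
#' @export
writeTrialTable <- function(records, path) {
  missing <- setdiff(trialTableCols, names(records))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  out <- records[, trialTableCols]
  for (col in c("wt_s", "md_s", "pa"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = which(
    trialTableCols %in% c("participant", "reason")))
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    participant = "character", trial = "integer", onset_sample = "integer",
    wt_s = "numeric", md_s = "numeric", pa = "numeric", score = "integer",
    excluded = "logical", reason = "character"))
  if (!identical(names(df), trialTableCols))
    stop("trial table at ", path, " does not match the expected schema")
  df
}

#' Persist a trained model bundle as JSON
#'
#' @param bundle A [ModelBundle-class].
#' @param path Output JSON path.
#' @return `writeModel`: `path` invisibly. `readModel`: the
#'   [ModelBundle-class], with full numeric precision.
#' @export
writeModel <- function(bundle, path) {
  obj <- list(
    accel_classifier = list(weights = bundle@accelClassifier$weights,
                            bias = bundle@accelClassifier$bias),
    selected_channels = bundle@selectedChannels,
    eeg_classifier = list(weights = bundle@eegClassifier$weights,
                          bias = bundle@eegClassifier$bias,
                          gamma = bundle@eegClassifier$gamma),
    calibration = list(mu0 = bundle@calibration$mu0,
                       sigma0 = bundle@calibration$sigma0))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("accel_classifier", "selected_channels", "eeg_classifier",
            "calibration")
  if (!all(need %in% names(obj)))
    stop("model file at ", path, " does not match the expected schema")
  new("ModelBundle",
      accelClassifier = list(weights = as.numeric(obj$accel_classifier$weights),
                             bias = as.numeric(obj$accel_classifier$bias)),
      selectedChannels = as.character(obj$selected_channels),
      eegClassifier = list(weights = as.numeric(obj$eeg_classifier$weights),
                           bias = as.numeric(obj$eeg_classifier$bias),
                           gamma = as.numeric(obj$eeg_classifier$gamma)),
      calibration = list(mu0 = as.numeric(obj$calibration$mu0),
                         sigma0 = as.numeric(obj$calibration$sigma0)))
}
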