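#' Construct a Recording
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param labels Channel names; defaults to the matrix rownames.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(200), 2), fs = 100, labels = c("Cz", "CPz"))
#' nSamples(rec)
#' @export
Recording <- function(data, fs, labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(labels))
    labels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- labels
  new("Recording", data = data, fs = as.numeric(fs),
      labels = as.character(labels))
}

#' Construct an EventList
#'
#' @param trialStart,pedalPress Integer vectors of 0-based sample indices,
#'   one entry per trial.
#' @return An [EventList-class] object.
#' @export
EventList <- function(trialStart, pedalPress) {
  new("EventList", trialStart = as.integer(trialStart),
      pedalPress = as.integer(pedalPress))
}

#' @rdname Recording-class
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)

#' @rdname Recording-class
#' @export
setMethod("channelLabels", "Recording", function(x) x@labels)

#' @rdname Recording-class
#' @export
setMethod("signalData", "Recording", function(x) x@data)

#' @rdname Recording-class
#' @export
setMethod("nChannels", "Recording", function(x) nrow(x@data))

#' @rdname Recording-class
#' @export
setMethod("nSamples", "Recording", function(x) ncol(x@data))

#' @rdname EventList-class
#' @export
setMethod("trialStarts", "EventList", function(x) x@trialStart)

#' @rdname EventList-class
#' @export
setMethod("pedalPresses", "EventList", function(x) x@pedalPress)

#' @rdname EventList-class
#' @export
setMethod("nTrials", "EventList", function(x) length(x@trialStart))

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nChannels(object), nSamples(object), samplingRate(object),
              nSamples(object) / samplingRate(object)))
  lab <- channelLabels(object)
  if (length(lab) > 8) lab <- c(lab[1:8], "...")
  cat("  channels:", paste(lab, collapse = " "), "\n")
})

setMethod("show", "EventList", function(object) {
  cat(sprintf("EventList: %d trials\n", nTrials(object)))
})

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle\n")
  cat(sprintf("  accelerometer classifier: 3 log-variance weights\n"))
  cat(sprintf("  selected channels (%d): %s\n",
              length(object@selectedChannels),
              paste(object@selectedChannels, collapse = " ")))
  cat(sprintf("  EEG classifier: %d weights, shrinkage gamma = %.3f\n",
              length(object@eegClassifier$weights),
              object@eegClassifier$gamma))
  cat(sprintf("  calibration: mu0 = %.4f, sigma0 = %.4f\n",
              object@calibration$mu0, object@calibration$sigma0))
})

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the mean across all channels. EEG sessions
#' are average-referenced on load; the original reference channel is not
#' reconstructed.
#'
#' @param rec A [Recording-class].
#' @return A `Recording` with zero channel-mean at every sample.
#' @export
commonAverageReference <- function(rec) {
  d <- signalData(rec)
  d <- sweep(d, 2, colMeans(d))
  Recording(d, samplingRate(rec), channelLabels(rec))
}

#' Extract a time-locked segment
#'
#' Slices the half-open window `[tLock + a, tLock + b)` (in ms, converted
#' to samples by `floor(ms * fs / 1000)`) from a recording. Windows are
#' sample-exact: `[-1000, -900)` followed by `[-900, 0)` concatenates to
#' `[-1000, 0)`.
#'
#' @param rec A [Recording-class].
#' @param tLock 0-based sample index the window is locked to.
#' @param windowMs Length-2 numeric `c(a, b)`, window in ms relative to
#'   `tLock`, half-open `[a, b)`.
#' @return Numeric matrix channels x samples (window length exactly
#'   `(b - a) * fs / 1000` samples).
#' @examples
#' rec <- Recording(matrix(seq_len(2000), 1), fs = 1000, labels = "Cz")
#' dim(sliceSegment(rec, 1500, c(-1000, 0)))
#' @export
sliceSegment <- function(rec, tLock, windowMs) {
  stopifnot(length(windowMs) == 2L)
  fs <- samplingRate(rec)
  from <- tLock + msToSamples(windowMs[1], fs)
  to <- tLock + msToSamples(windowMs[2], fs)  # exclusive
  if (to <= from)
    stop("empty segment: window [", windowMs[1], ", ", windowMs[2],
         ") ms has no samples")
  if (from < 0 || to > nSamples(rec))
    stop("segment [", from, ", ", to, ") out of recording bounds [0, ",
         nSamples(rec), ")")
  signalData(rec)[, (from + 1L):to, drop = FALSE]
}
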