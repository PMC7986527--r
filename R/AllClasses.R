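#' @import methods
NULL

#' Continuous multi-channel recording
#'
#' Container for a continuous multi-channel signal sampled at a fixed rate:
#' either EEG (microvolts) or 3-axis accelerometry (device units). Samples
#' are indexed 0-based throughout the package, so that a marker at sample
#' `t` refers to the `(t+1)`-th column of `signalData()`.
#'
#' @slot data Numeric matrix, channels x samples.
#' @slot fs Sampling rate in Hz.
#' @slot labels Character vector of unique channel names, one per row.
#'
#' @seealso [Recording()], [sliceSegment()], [readRecording()]
#' @export
setClass("Recording",
  representation(data = "matrix", fs = "numeric", labels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive finite number")
    if (nrow(object@data) != length(object@labels))
      msg <- c(msg, "number of labels must equal number of channels (rows)")
    if (anyDuplicated(object@labels))
      msg <- c(msg, "channel labels must be unique")
    if (any(!is.finite(object@data)))
      msg <- c(msg, "signal contains non-finite samples")
    if (length(msg)) msg else TRUE
  }
)

#' Per-trial event markers
#'
#' Paired sample indices (0-based) of the trial-start cue and the pedal
#' press for every trial of a session. Trials are strictly ordered in time
#' and every press follows its own trial start.
#'
#' @slot trialStart Integer vector of trial-start sample indices.
#' @slot pedalPress Integer vector of pedal-press sample indices.
#'
#' @seealso [EventList()]
#' @export
setClass("EventList",
  representation(trialStart = "integer", pedalPress = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@trialStart) != length(object@pedalPress))
      msg <- c(msg, "trialStart and pedalPress must have equal length")
    else if (length(object@trialStart)) {
      if (any(object@pedalPress <= object@trialStart))
        msg <- c(msg, "every pedal press must come after its trial start")
      merged <- as.vector(rbind(object@trialStart, object@pedalPress))
      if (is.unsorted(merged, strictly = TRUE))
        msg <- c(msg, "events must be strictly increasing across trials")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Trained model bundle for the feedback stage
#'
#' Everything learned from a preparatory session that the feedback stage
#' needs: the accelerometer movement/idle classifier, the RP-informative
#' channel subset, the shrinkage-LDA EEG classifier, and the score
#' calibration (mean and SD of leave-one-out classifier outputs on
#' movement-onset segments).
#'
#' @slot accelClassifier List with `weights` (length 3) and `bias`.
#' @slot selectedChannels Character vector of selected EEG channel labels.
#' @slot eegClassifier List with `weights` (length 10 per channel), `bias`
#'   and `gamma` (shrinkage intensity in \[0, 1\]).
#' @slot calibration List with `mu0` and `sigma0` (> 0).
#'
#' @seealso [trainModelBundle()], [writeModel()]
#' @export
setClass("ModelBundle",
  representation(accelClassifier = "list", selectedChannels = "character",
                 eegClassifier = "list", calibration = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@selectedChannels) < 1L)
      msg <- c(msg, "selectedChannels must be non-empty")
    cal <- object@calibration
    if (!is.numeric(cal$sigma0) || cal$sigma0 <= 0)
      msg <- c(msg, "calibration sigma0 must be > 0")
    if (length(object@accelClassifier$weights) != 3L)
      msg <- c(msg, "accelClassifier weights must have length 3")
    nw <- length(object@eegClassifier$weights)
    if (nw != 10L * length(object@selectedChannels))
      msg <- c(msg, sprintf(
        "eegClassifier weight length (%d) must be 10 x number of selected channels (%d)",
        nw, length(object@selectedChannels)))
    g <- object@eegClassifier$gamma
    if (!is.numeric(g) || g < 0 || g > 1)
      msg <- c(msg, "shrinkage intensity gamma must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)
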