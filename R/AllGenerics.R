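#' @rdname Recording-class
#' @param object,x A `Recording` or `EventList`.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname Recording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname Recording-class
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname Recording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname Recording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EventList-class
#' @export
setGeneric("trialStarts", function(x) standardGeneric("trialStarts"))

#' @rdname EventList-class
#' @export
setGeneric("pedalPresses", function(x) standardGeneric("pedalPresses"))

#' @rdname EventList-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
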