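## Causal replay of the feedback stage: both classifiers are evaluated on
## a 20-ms grid of window-end times using only data available at each
## instant; at the pedal press the accelerometer outputs are scanned
## backward along the grid to the latest grid point classified idle, and
## the feedback score is the EEG output whose window ends there.

#' Feedback-stage configuration
#'
#' @param cadenceMs Classifier evaluation cadence (default 20 ms).
#' @param accelWindowMs Accelerometer window length (default 200 ms).
#' @param eegWindowMs EEG window length (default 1000 ms).
#' @param varianceSdMult Multiphasic exclusion threshold: pre-onset
#'   accelerometer variance above `mean + mult * SD` of the resting
#'   baseline (default 3).
#' @param minWtMs Premature-trial threshold: excluded iff WT is strictly
#'   below this (default 1000 ms).
#' @param maxExcludedFraction Participant exclusion: dropped iff the
#'   excluded-trial fraction strictly exceeds this (default 0.5).
#' @return A validated list of class `FeedbackConfig`.
#' @export
feedbackConfig <- function(cadenceMs = 20, accelWindowMs = 200,
                           eegWindowMs = 1000, varianceSdMult = 3,
                           minWtMs = 1000, maxExcludedFraction = 0.5) {
  stopifnot(cadenceMs > 0, accelWindowMs > 0, eegWindowMs > 0,
            varianceSdMult > 0, minWtMs > 0, maxExcludedFraction > 0)
  structure(list(cadenceMs = cadenceMs, accelWindowMs = accelWindowMs,
                 eegWindowMs = eegWindowMs, varianceSdMult = varianceSdMult,
                 minWtMs = minWtMs,
                 maxExcludedFraction = maxExcludedFraction),
            class = "FeedbackConfig")
}

#' Replay the feedback stage of a session
#'
#' Per trial: the accelerometer classifier is evaluated at every grid
#' point (multiples of the cadence, anchored at recording start) from the
#' pedal press backward; the latest grid point classified idle is the
#' online movement onset, and the feedback score is the EEG classifier
#' output for the 1000-ms window ending at that grid point, mapped
#' through [transformScore()]. WT and MD are reported in seconds, PA as
#' the maximum Euclidean norm of the mean-centered 3-axis acceleration
#' between onset and press.
#'
#' Degenerate trials are flagged: `no_movement_detected` (already idle at
#' the press; onset = press, score computed at the last grid point before
#' the press), `no_idle_found` (onset = trial start), and `unusable`
#' (score window would start before the recording; score is `NA`).
#'
#' @param eeg,accel [Recording-class] objects on a common time base.
#' @param events [EventList-class] of the feedback trials.
#' @param bundle Trained [ModelBundle-class].
#' @param cfg A [feedbackConfig()].
#' @return Data frame with `trial`, `onset_sample`, `wt_s`, `md_s`, `pa`,
#'   `score`, `flag`.
#' @export
runFeedbackStage <- function(eeg, accel, events, bundle,
                             cfg = feedbackConfig()) {
  fs <- samplingRate(accel)
  stopifnot(samplingRate(eeg) == fs)
  step <- cfg$cadenceMs * fs / 1000
  if (step != round(step) || step < 1)
    stop("cadence of ", cfg$cadenceMs, " ms does not fall on the sample ",
         "grid at ", fs, " Hz")
  step <- as.integer(step)
  wAcc <- msToSamples(cfg$accelWindowMs, fs)
  wEeg <- msToSamples(cfg$eegWindowMs, fs)
  accClf <- bundle@accelClassifier
  eegClf <- bundle@eegClassifier
  channels <- bundle@selectedChannels
  cal <- bundle@calibration
  accData <- signalData(accel)

  starts <- trialStarts(events); presses <- pedalPresses(events)
  rows <- lapply(seq_len(nTrials(events)), function(i) {
    start <- starts[i]; press <- presses[i]
    gridPress <- (press %/% step) * step
    minE <- as.integer(ceiling((start + wAcc) / step)) * step
    flag <- NA_character_
    if (gridPress < minE) {
      onset <- start; scoreAt <- gridPress; flag <- "no_idle_found"
    } else {
      ends <- seq.int(gridPress, minE, by = -step)
      outs <- vapply(ends, function(e) {
        f <- logvarFeatures(accData[, (e - wAcc + 1L):e, drop = FALSE],
                            fs, cfg$accelWindowMs)
        sum(accClf$weights * f) + accClf$bias
      }, 0)
      idle <- outs <= 0
      if (idle[1L]) {
        onset <- press; scoreAt <- gridPress
        flag <- "no_movement_detected"
      } else if (!any(idle)) {
        onset <- start; scoreAt <- minE; flag <- "no_idle_found"
      } else {
        onset <- ends[which(idle)[1L]]
        scoreAt <- onset
      }
    }
    score <- NA_integer_
    if (scoreAt - wEeg < 0) {
      flag <- "unusable"
    } else {
      x <- sum(eegClf$weights * extractFeatures(eeg, scoreAt, channels)) +
        eegClf$bias
      score <- transformScore(x, cal)
    }
    span <- accData[, (onset + 1L):(press + 1L), drop = FALSE]
    centered <- span - rowMeans(span)
    pa <- sqrt(max(colSums(centered^2)))
    data.frame(trial = i, onset_sample = as.integer(onset),
               wt_s = (onset - start) / fs, md_s = (press - onset) / fs,
               pa = pa, score = score, flag = flag)
  })
  do.call(rbind, rows)
}

#' Apply the trial exclusion rules
#'
#' Flags `multiphasic` trials (summed-axis accelerometer variance in the
#' 1000 ms before the assigned onset exceeds `mean + mult * SD` of the
#' preparatory resting baseline) and `premature` trials (WT strictly
#' below 1000 ms); both flags can co-occur. An onset closer than 1000 ms
#' to the recording start is an error (the variance window would be
#' truncated), except for trials already flagged unusable.
#'
#' @param records Trial records from [runFeedbackStage()].
#' @param accel 3-axis [Recording-class] of the same session.
#' @param baselineVar List with `mean` and `sd` from
#'   [baselineAccelVariance()] of the preparatory stage.
#' @param cfg A [feedbackConfig()].
#' @return `records` with added `excluded` (logical) and `reason`
#'   (comma-separated codes, `""` if kept) columns.
#' @export
applyTrialExclusions <- function(records, accel, baselineVar,
                                 cfg = feedbackConfig()) {
  fs <- samplingRate(accel)
  w1000 <- msToSamples(1000, fs)
  threshold <- baselineVar$mean + cfg$varianceSdMult * baselineVar$sd
  data <- signalData(accel)
  n <- nrow(records)
  reason <- character(n)
  for (i in seq_len(n)) {
    codes <- character()
    if (!is.na(records$flag[i]) && records$flag[i] == "unusable") {
      codes <- "unusable"
    } else {
      onset <- records$onset_sample[i]
      if (onset - w1000 < 0)
        stop("trial ", records$trial[i], ": pre-onset variance window ",
             "would be truncated at the recording start")
      seg <- data[, (onset - w1000 + 1L):onset, drop = FALSE]
      if (sum(apply(seg, 1, stats::var)) > threshold)
        codes <- c(codes, "multiphasic")
      if (records$wt_s[i] * 1000 < cfg$minWtMs)
        codes <- c(codes, "premature")
    }
    reason[i] <- paste(codes, collapse = ",")
  }
  records$excluded <- nzchar(reason)
  records$reason <- reason
  records
}

#' Apply the participant exclusion rule
#'
#' Drops every participant whose fraction of excluded trials strictly
#' exceeds `maxExcludedFraction` (default 0.5, i.e. more than half).
#'
#' @param records Data frame with `participant` and `excluded` columns
#'   (all participants row-bound).
#' @param cfg A [feedbackConfig()].
#' @return Character vector of kept participant identifiers.
#' @export
applyParticipantExclusion <- function(records, cfg = feedbackConfig()) {
  stopifnot(nrow(records) >= 1L)
  frac <- tapply(records$excluded, records$participant, mean)
  names(frac)[frac <= cfg$maxExcludedFraction]
}
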