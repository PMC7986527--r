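## Accelerometer movement-onset detection: a linear classifier on
## per-axis log-variance features separates "movement" windows (the
## 200 ms before a pedal press) from "idle" windows (300-500 ms after
## the cue), and a backward sample-wise search from the press finds the
## last window with no evidence of movement.

LOGVAR_EPS <- 1e-12  # variance floor (device units^2) so the log is total

#' Log-variance features of an accelerometer window
#'
#' Per-axis `ln(var + eps)` of a 200-ms 3-axis window, with
#' `eps = 1e-12` so constant windows give a finite feature.
#'
#' @param window Numeric matrix, 3 axes x window samples (exactly
#'   `windowMs * fs / 1000` samples).
#' @param fs Sampling rate in Hz.
#' @param windowMs Expected window length in ms (default 200).
#' @return Numeric length-3 feature vector.
#' @examples
#' logvarFeatures(matrix(0, 3, 200), fs = 1000)  # ~ -27.63 per axis
#' @export
logvarFeatures <- function(window, fs, windowMs = 200) {
  expected <- msToSamples(windowMs, fs)
  if (!is.matrix(window) || nrow(window) != 3L || ncol(window) != expected)
    stop("window must be 3 x ", expected, " samples (", windowMs, " ms at ",
         fs, " Hz), got ", paste(dim(window), collapse = " x "))
  log(apply(window, 1, stats::var) + LOGVAR_EPS)
}

## LDA with pooled within-class covariance and equal priors; classifier
## output f(x) = w'x + b with the positive class first.
ldaTrain <- function(xPos, xNeg, featureNames = NULL) {
  if (nrow(xPos) < 2L || nrow(xNeg) < 2L)
    stop("need at least 2 examples per class")
  mPos <- colMeans(xPos); mNeg <- colMeans(xNeg)
  cPos <- sweep(xPos, 2, mPos); cNeg <- sweep(xNeg, 2, mNeg)
  pooled <- (crossprod(cPos) + crossprod(cNeg)) /
    (nrow(xPos) + nrow(xNeg) - 2)
  v <- diag(pooled)
  deg <- which(v <= .Machine$double.eps * max(v, 1))
  if (length(deg)) {
    nm <- if (is.null(featureNames)) paste0("feature ", deg)
          else featureNames[deg]
    stop("singular pooled covariance; degenerate (zero-variance) ",
         "dimension(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  ## rank deficiency from very few examples: Moore-Penrose fallback
  w <- tryCatch(solve(pooled, mPos - mNeg),
                error = function(e) pseudoSolve(pooled, mPos - mNeg))
  list(weights = as.numeric(w),
       bias = -sum(w * (mPos + mNeg) / 2))
}

ldaApply <- function(clf, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.numeric(x %*% clf$weights + clf$bias)
}

#' Train the accelerometer movement/idle classifier
#'
#' Linear discriminant (pooled covariance, equal priors) on log-variance
#' features. Output convention: `> 0` means movement; the orientation is
#' guaranteed, i.e. the mean output on the movement class exceeds the
#' mean output on the idle class.
#'
#' @param movementWindows,idleWindows Lists of 3 x window matrices (see
#'   [logvarFeatures()]), at least 2 per class.
#' @param fs Sampling rate in Hz.
#' @param windowMs Window length in ms (default 200).
#' @return List with `weights` (length 3) and `bias`.
#' @export
trainAccelClassifier <- function(movementWindows, idleWindows, fs,
                                 windowMs = 200) {
  fPos <- t(vapply(movementWindows, logvarFeatures, numeric(3),
                   fs = fs, windowMs = windowMs))
  fNeg <- t(vapply(idleWindows, logvarFeatures, numeric(3),
                   fs = fs, windowMs = windowMs))
  ldaTrain(fPos, fNeg, featureNames = c("accX", "accY", "accZ"))
}

## Rolling per-axis log-variance features for every window END position.
## Returns a 3 x (nSamples+1) matrix: column e+1 holds the features of the
## half-open window [e - win, e), defined for e in [win, nSamples].
rollingLogVar <- function(data, win) {
  n <- ncol(data)
  out <- matrix(NA_real_, 3, n + 1L)
  for (ax in 1:3) {
    x <- data[ax, ]
    cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
    e <- win:n
    s <- cs[e + 1L] - cs[e - win + 1L]
    s2 <- cs2[e + 1L] - cs2[e - win + 1L]
    v <- pmax(0, (s2 - s^2 / win) / (win - 1))
    out[ax, e + 1L] <- log(v + LOGVAR_EPS)
  }
  out
}

#' Backward search for movement onset
#'
#' Slides a 200-ms window ending at the pedal press back one sample at a
#' time and stops at the first window the classifier labels idle; the END
#' sample of that window is the movement onset (the last instant with no
#' evidence of movement). Degenerate cases are flagged rather than
#' errored: if the window ending at the press is already idle, the press
#' sample is returned with flag `no_movement_detected`; if no idle window
#' exists down to the trial start, the trial-start sample is returned
#' with flag `no_idle_found`.
#'
#' @param accel 3-axis accelerometer [Recording-class].
#' @param pressSample,trialStartSample 0-based sample indices.
#' @param clf Classifier from [trainAccelClassifier()].
#' @param windowMs Window length in ms (default 200).
#' @return List with `onset` (0-based sample) and `flag` (`NA_character_`
#'   when a regular onset was found).
#' @export
backwardSearchOnset <- function(accel, pressSample, clf, trialStartSample,
                                windowMs = 200) {
  fs <- samplingRate(accel)
  win <- msToSamples(windowMs, fs)
  if (pressSample - trialStartSample < win)
    stop("press must be at least one window (", win,
         " samples) after trial start")
  data <- signalData(accel)
  feats <- rollingLogVar(
    data[, (trialStartSample + 1L):pressSample, drop = FALSE], win)
  ## column j of feats = window ending at trialStartSample + j - 1
  ends <- pressSample:(trialStartSample + win)
  cols <- ends - trialStartSample + 1L
  outs <- as.numeric(clf$weights %*% feats[, cols] + clf$bias)
  idle <- outs <= 0
  if (idle[1L])
    return(list(onset = pressSample, flag = "no_movement_detected"))
  k <- which(idle)[1L]
  if (is.na(k))
    return(list(onset = trialStartSample, flag = "no_idle_found"))
  list(onset = ends[k], flag = NA_character_)
}

## Extract training windows of a preparatory session: movement =
## [-200, 0) ms before each press, idle = [300, 500) ms after each cue.
sessionAccelWindows <- function(accel, events, windowMs = 200) {
  fs <- samplingRate(accel)
  list(
    movement = lapply(pedalPresses(events), function(p)
      sliceSegment(accel, p, c(-windowMs, 0))),
    idle = lapply(trialStarts(events), function(s)
      sliceSegment(accel, s, c(300, 300 + windowMs)))
  )
}

#' Leave-one-out movement onsets for a preparatory session
#'
#' For each trial, trains the accelerometer classifier on the movement
#' and idle windows of all other trials and runs the backward search on
#' the held-out trial.
#'
#' @param accel 3-axis [Recording-class].
#' @param events [EventList-class] with at least 3 trials.
#' @param windowMs Window length in ms.
#' @return Data frame with `trial`, `onset` (0-based sample) and `flag`.
#' @export
looOnsets <- function(accel, events, windowMs = 200) {
  n <- nTrials(events)
  if (n < 3L) stop("need at least 3 trials for leave-one-out onsets")
  fs <- samplingRate(accel)
  wins <- sessionAccelWindows(accel, events, windowMs)
  fMov <- t(vapply(wins$movement, logvarFeatures, numeric(3),
                   fs = fs, windowMs = windowMs))
  fIdl <- t(vapply(wins$idle, logvarFeatures, numeric(3),
                   fs = fs, windowMs = windowMs))
  starts <- trialStarts(events); presses <- pedalPresses(events)
  res <- lapply(seq_len(n), function(i) {
    clf <- ldaTrain(fMov[-i, , drop = FALSE], fIdl[-i, , drop = FALSE],
                    featureNames = c("accX", "accY", "accZ"))
    backwardSearchOnset(accel, presses[i], clf, starts[i], windowMs)
  })
  data.frame(trial = seq_len(n),
             onset = vapply(res, `[[`, 0L, "onset"),
             flag = vapply(res, `[[`, "", "flag"))
}

#' Onset-latency outlier mask
#'
#' Single-pass 3-SD rule on onset latencies (press minus onset): a trial
#' is dropped iff its latency lies more than 3 population SDs from the
#' mean. The rule is applied once; statistics are not recomputed on the
#' kept trials. Zero SD (all latencies equal) keeps everything.
#'
#' @param latencies Numeric vector (>= 2 values) of onset latencies.
#' @param nSd Multiplier (default 3).
#' @return Logical keep mask of the same length.
#' @export
onsetOutlierMask <- function(latencies, nSd = 3) {
  if (length(latencies) < 2L) stop("need at least 2 latencies")
  s <- popSd(latencies)
  if (s == 0) return(rep(TRUE, length(latencies)))
  abs(latencies - mean(latencies)) <= nSd * s
}

#' Baseline accelerometer variance at rest
#'
#' Per trial, the summed-across-axes variance of the idle window
#' (300-500 ms after the cue); returns the mean and SD of these per-trial
#' variances across trials. Used as the reference for the multiphasic
#' trial-exclusion criterion in the feedback stage.
#'
#' @param accel 3-axis [Recording-class].
#' @param events [EventList-class] with >= 2 trials.
#' @param windowMs Idle window length in ms.
#' @return List with `mean` and `sd`.
#' @export
baselineAccelVariance <- function(accel, events, windowMs = 200) {
  if (nTrials(events) < 2L) stop("need at least 2 preparatory trials")
  v <- vapply(trialStarts(events), function(s) {
    seg <- sliceSegment(accel, s, c(300, 300 + windowMs))
    sum(apply(seg, 1, stats::var))
  }, 0)
  list(mean = mean(v), sd = stats::sd(v))
}
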