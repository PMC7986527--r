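## Single-trial RP scoring: select RP-informative channels by a
## segment-change statistic, extract spatiotemporal 100-ms-bin features,
## train a shrinkage-regularized LDA, calibrate its output distribution
## by leave-one-out, and map outputs to integer feedback scores.

#' Segment-change statistic
#'
#' How much a 1000-ms single-channel segment changed: the mean over its
#' last 200 ms minus the mean over its first 200 ms, oriented so that a
#' negative-going RP yields a negative value.
#'
#' @param segment Numeric vector of exactly `1000 * fs / 1000` samples.
#' @param fs Sampling rate in Hz.
#' @return Change in microvolts (0 for a constant segment).
#' @examples
#' segmentChange(seq(0, -10, length.out = 1000), fs = 1000)  # -8 uV
#' @export
segmentChange <- function(segment, fs) {
  n <- msToSamples(1000, fs)
  if (length(segment) != n)
    stop("segment must have exactly ", n, " samples (1000 ms at ", fs, " Hz)")
  w <- msToSamples(200, fs)
  mean(segment[(n - w + 1L):n]) - mean(segment[1:w])
}

## Delta values for all channels over a set of lock points:
## channels x trials matrix of segment changes on [-1000, 0) ms windows.
segmentChanges <- function(eeg, lockSamples) {
  fs <- samplingRate(eeg)
  w <- msToSamples(200, fs)
  n1000 <- msToSamples(1000, fs)
  vapply(lockSamples, function(t) {
    seg <- sliceSegment(eeg, t, c(-1000, 0))
    rowMeans(seg[, (n1000 - w + 1L):n1000, drop = FALSE]) -
      rowMeans(seg[, 1:w, drop = FALSE])
  }, numeric(nChannels(eeg)))
}

#' Select RP-informative EEG channels
#'
#' Per channel, two one-sided t-tests on the segment-change statistic of
#' the preparatory trials: (A) a one-sample test that the change before
#' movement onset is below zero (the negative-going RP), and (B) a paired
#' test that the change before movement onset is below the change before
#' the trial-start cue of the same trial (guarding against global
#' negative drifts). A channel is selected iff both reject at level
#' `alpha`. A channel with zero-variance statistics is never selected
#' (its t-test is undefined).
#'
#' @param eeg EEG [Recording-class] (all channels).
#' @param events [EventList-class] of the kept preparatory trials.
#' @param onsets 0-based movement-onset samples, one per kept trial.
#' @param alpha Test level (default 0.05).
#' @param forceCz If `TRUE` and no channel passes, fall back to Cz with a
#'   warning instead of erroring.
#' @return Character vector of selected channel labels.
#' @export
selectChannels <- function(eeg, events, onsets, alpha = 0.05,
                           forceCz = FALSE) {
  if (nTrials(events) < 3L || length(onsets) != nTrials(events))
    stop("need >= 3 kept trials with one onset per trial")
  dMove <- segmentChanges(eeg, onsets)
  dCue <- segmentChanges(eeg, trialStarts(events))
  labs <- channelLabels(eeg)
  sel <- vapply(seq_along(labs), function(ch) {
    pA <- tryCatch(
      stats::t.test(dMove[ch, ], mu = 0, alternative = "less")$p.value,
      error = function(e) NA_real_)
    pB <- tryCatch(
      stats::t.test(dMove[ch, ] - dCue[ch, ], mu = 0,
                    alternative = "less")$p.value,
      error = function(e) NA_real_)
    isTRUE(pA < alpha) && isTRUE(pB < alpha)
  }, logical(1))
  out <- labs[sel]
  if (!length(out)) {
    if (forceCz && "Cz" %in% labs) {
      warning("no channel passed both selection tests; falling back to Cz")
      return("Cz")
    }
    stop("no channel passed both selection tests; review the signal-to-",
         "noise level or the session configuration")
  }
  out
}

#' Spatiotemporal RP feature vector
#'
#' For the 1000-ms window preceding `tLock`: per channel, subtract the
#' baseline (mean over \[-1000, -900) ms) and average 10 consecutive
#' 100-ms bins; features are concatenated channel-major, so the first
#' feature of every channel is 0 by construction.
#'
#' @param eeg EEG [Recording-class].
#' @param tLock 0-based sample index (movement onset or trial start).
#' @param channels Channel labels to include, in order.
#' @return Numeric vector of length `10 * length(channels)`.
#' @export
extractFeatures <- function(eeg, tLock, channels) {
  idx <- match(channels, channelLabels(eeg))
  if (anyNA(idx))
    stop("unknown channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  seg <- sliceSegment(eeg, tLock, c(-1000, 0))[idx, , drop = FALSE]
  fs <- samplingRate(eeg)
  binLen <- msToSamples(100, fs)
  bin <- rep(1:10, each = binLen)
  binMeans <- t(apply(seg, 1, function(x) tapply(x, bin, mean)))
  feats <- binMeans - binMeans[, 1L]
  as.vector(t(feats))
}

#' Ledoit-Wolf shrinkage intensity
#'
#' Analytic shrinkage of a sample covariance toward the scaled identity
#' `nu * I` with `nu = mean(diag(S))`: the intensity minimizing the
#' expected Frobenius loss, clamped to \[0, 1\].
#'
#' @param xc Numeric matrix of centered observations (rows).
#' @return List with `gamma` (intensity), `cov` (the shrunk covariance)
#'   and `nu`.
#' @references Ledoit & Wolf (2004), J. Multivariate Analysis 88:365-411.
#' @export
ledoitWolfShrinkage <- function(xc) {
  n <- nrow(xc); d <- ncol(xc)
  s <- crossprod(xc) / n
  nu <- mean(diag(s))
  s2 <- sum(s^2)
  d2 <- s2 - 2 * nu * sum(diag(s)) + d * nu^2  # ||S - nu I||_F^2
  rs <- rowSums(xc^2)
  b2bar <- (sum(rs^2) - n * s2) / n^2          # avg ||x x' - S||_F^2 / n
  gamma <- if (d2 > 0) min(1, max(0, min(b2bar, d2) / d2)) else 0
  shrunk <- (1 - gamma) * s
  diag(shrunk) <- diag(shrunk) + gamma * nu
  list(gamma = gamma, cov = shrunk, nu = nu)
}

#' Train the shrinkage-LDA RP classifier
#'
#' Linear discriminant on spatiotemporal features whose pooled
#' within-class covariance is shrunk toward `nu * I` with an analytically
#' chosen (Ledoit-Wolf) intensity. Oriented so that the movement-onset
#' class has the larger output. The identically-zero first bin per
#' channel is retained; under shrinkage the pooled covariance stays
#' invertible and the zero-variance features get negligible weight.
#'
#' @param onsetFeatures,cueFeatures Numeric matrices (trials x features)
#'   of movement-onset and trial-start feature vectors, >= 2 rows each.
#' @return List with `weights`, `bias` and `gamma`.
#' @export
trainRpLda <- function(onsetFeatures, cueFeatures) {
  if (nrow(onsetFeatures) < 2L || nrow(cueFeatures) < 2L)
    stop("need at least 2 examples per class")
  if (ncol(onsetFeatures) != ncol(cueFeatures))
    stop("feature dimension mismatch between classes")
  m1 <- colMeans(onsetFeatures); m0 <- colMeans(cueFeatures)
  xc <- rbind(sweep(onsetFeatures, 2, m1), sweep(cueFeatures, 2, m0))
  lw <- ledoitWolfShrinkage(xc)
  w <- tryCatch(solve(lw$cov, m1 - m0), error = function(e)
    stop("shrunk covariance is singular (degenerate training data)",
         call. = FALSE))
  list(weights = as.numeric(w), bias = -sum(w * (m1 + m0) / 2),
       gamma = lw$gamma)
}

#' Leave-one-out score calibration
#'
#' For every preparatory trial, trains the RP classifier on the
#' movement-onset and trial-start segments of all other trials and
#' applies it to the held-out movement-onset segment, yielding one
#' output per single-trial RP. The mean and SD of this distribution are
#' the calibration (mu0, sigma0) of the feedback score transform.
#'
#' @param eeg EEG [Recording-class].
#' @param events [EventList-class] of kept trials (>= 3).
#' @param onsets Movement-onset samples (0-based), one per trial.
#' @param channels Selected channel labels.
#' @return List with `mu0`, `sigma0` (sample SD, must be > 0) and
#'   `outputs` (the per-trial leave-one-out outputs).
#' @export
looCalibration <- function(eeg, events, onsets, channels) {
  n <- nTrials(events)
  if (n < 3L) stop("need at least 3 trials for leave-one-out calibration")
  fOn <- t(vapply(onsets, extractFeatures, numeric(10 * length(channels)),
                  eeg = eeg, channels = channels))
  fCue <- t(vapply(trialStarts(events), extractFeatures,
                   numeric(10 * length(channels)),
                   eeg = eeg, channels = channels))
  outs <- vapply(seq_len(n), function(i) {
    clf <- trainRpLda(fOn[-i, , drop = FALSE], fCue[-i, , drop = FALSE])
    sum(clf$weights * fOn[i, ]) + clf$bias
  }, 0)
  sigma0 <- stats::sd(outs)
  if (!is.finite(sigma0) || sigma0 <= .Machine$double.eps * max(abs(outs), 1))
    stop("sigma0 is zero: leave-one-out outputs are degenerate, ",
         "scores would be undefined")
  list(mu0 = mean(outs), sigma0 = sigma0, outputs = outs)
}

#' Map a classifier output to a feedback score
#'
#' `score = round(((x - mu0) / sigma0) * 15 + 50)`, rounded half away
#' from zero. An average output gives 50; one calibration SD above or
#' below gives 65 or 35.
#'
#' @param x Classifier output(s).
#' @param calibration List with `mu0` and `sigma0` (> 0), e.g. from
#'   [looCalibration()].
#' @return Integer score(s).
#' @examples
#' transformScore(c(0, 1, -1), list(mu0 = 0, sigma0 = 1))  # 50 65 35
#' @export
transformScore <- function(x, calibration) {
  if (calibration$sigma0 <= 0) stop("sigma0 must be > 0")
  as.integer(roundHalfAway(
    ((x - calibration$mu0) / calibration$sigma0) * 15 + 50))
}

#' Train the full preparatory-stage model bundle
#'
#' Runs the complete preparatory-stage pipeline on one session:
#' leave-one-out movement onsets with the 3-SD latency outlier exclusion,
#' the final accelerometer classifier on the kept trials, channel
#' selection, the shrinkage-LDA EEG classifier on all kept trials, the
#' leave-one-out score calibration, and the resting accelerometer
#' baseline variance used by the feedback-stage exclusion rule.
#'
#' @param eeg,accel [Recording-class] objects sharing a time base.
#' @param events [EventList-class] of the preparatory trials.
#' @param alpha Channel-selection test level.
#' @param forceCz Passed to [selectChannels()].
#' @return List with `bundle` ([ModelBundle-class]), `baselineVar` (from
#'   [baselineAccelVariance()]), `onsets` (the leave-one-out onset table)
#'   and `kept` (logical mask of trials surviving onset detection and
#'   the outlier rule).
#' @export
trainModelBundle <- function(eeg, accel, events, alpha = 0.05,
                             forceCz = FALSE) {
  onsetTab <- looOnsets(accel, events)
  ok <- is.na(onsetTab$flag)
  latencies <- pedalPresses(events) - onsetTab$onset
  keep <- ok
  if (sum(ok) >= 2L)
    keep[ok] <- onsetOutlierMask(latencies[ok])
  if (sum(keep) < 3L)
    stop("fewer than 3 preparatory trials survive onset detection")
  keptEvents <- EventList(trialStarts(events)[keep],
                          pedalPresses(events)[keep])
  keptOnsets <- onsetTab$onset[keep]

  wins <- sessionAccelWindows(accel, keptEvents)
  accelClf <- trainAccelClassifier(wins$movement, wins$idle,
                                   samplingRate(accel))
  channels <- selectChannels(eeg, keptEvents, keptOnsets, alpha = alpha,
                             forceCz = forceCz)
  cal <- looCalibration(eeg, keptEvents, keptOnsets, channels)
  fOn <- t(vapply(keptOnsets, extractFeatures,
                  numeric(10 * length(channels)),
                  eeg = eeg, channels = channels))
  fCue <- t(vapply(trialStarts(keptEvents), extractFeatures,
                   numeric(10 * length(channels)),
                   eeg = eeg, channels = channels))
  eegClf <- trainRpLda(fOn, fCue)

  bundle <- new("ModelBundle",
    accelClassifier = accelClf,
    selectedChannels = channels,
    eegClassifier = eegClf,
    calibration = list(mu0 = cal$mu0, sigma0 = cal$sigma0))
  list(bundle = bundle,
       baselineVar = baselineAccelVariance(accel, keptEvents),
       onsets = onsetTab, kept = keep)
}
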