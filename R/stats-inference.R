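## Two-level (summary-statistic) inference on trial-wise feedback scores:
## per-participant OLS on z-scored covariates, second-level one-sample
## t-tests across participants, and JZS Bayes factors quantifying
## evidence of absence.

zScore <- function(x) (x - mean(x)) / stats::sd(x)

#' Trial-wise regression of feedback scores
#'
#' Ordinary least squares of a participant's feedback scores on their
#' z-scored trial number (TN), waiting time (WT), movement duration (MD)
#' and peak acceleration (PA) plus a constant. Covariates are z-scored
#' within the participant over the supplied (kept) trials.
#'
#' @param records Data frame with columns `trial`, `wt_s`, `md_s`, `pa`,
#'   `score` and optionally `excluded` (excluded rows are dropped); at
#'   least 6 kept trials.
#' @return Named numeric coefficients `c(tn, wt, md, pa, intercept)`.
#' @export
fitTrialwiseRegression <- function(records) {
  if (!is.null(records$excluded)) records <- records[!records$excluded, ]
  if (nrow(records) < 6L) stop("need at least 6 kept trials")
  x <- cbind(tn = zScore(records$trial), wt = zScore(records$wt_s),
             md = zScore(records$md_s), pa = zScore(records$pa),
             intercept = 1)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(as.numeric(qr.coef(qrx, records$score)), colnames(x))
}

#' Second-level one-sample t-test
#'
#' Tests per-participant regression coefficients against zero across
#' participants. The directional variant reports
#' `p = P(T_df <= t_obs)` for the "smaller than zero" alternative.
#'
#' @param coefs Numeric vector of per-participant coefficients (>= 2).
#' @param side `"two_sided"` or `"negative_one_sided"`.
#' @return List with `t`, `df` and `p`.
#' @export
secondLevelTTest <- function(coefs,
                             side = c("two_sided", "negative_one_sided")) {
  side <- match.arg(side)
  n <- length(coefs)
  if (n < 2L) stop("need at least 2 participants")
  s <- stats::sd(coefs)
  if (s == 0) stop("zero variance across participants")
  t <- mean(coefs) / (s / sqrt(n))
  df <- n - 1L
  p <- if (side == "negative_one_sided") stats::pt(t, df)
       else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Default Bayes factor in favor of the null (`BF01`, or `BF0-` for the
#' directional test) given an observed t statistic: the central-t density
#' of the data under the null divided by the marginal likelihood under a
#' Cauchy(0, r) prior on the standardized effect size, computed by
#' adaptive quadrature. For the `negative_one_sided` test the prior is
#' truncated to negative effects and renormalized.
#'
#' @param t Observed t statistic.
#' @param n Sample size (df = n - 1, >= 2).
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @param side `"two_sided"` or `"negative_one_sided"`.
#' @return The Bayes factor (null over alternative), a positive scalar.
#' @examples
#' jzsBayesFactor(0.103, 19, side = "negative_one_sided")  # ~4.54
#' @export
jzsBayesFactor <- function(t, n, r = sqrt(2) / 2,
                           side = c("two_sided", "negative_one_sided")) {
  side <- match.arg(side)
  stopifnot(n >= 2, r > 0)
  df <- n - 1
  m0 <- stats::dt(t, df)
  integrand <- function(delta)
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, r)
  m1 <- if (side == "two_sided") {
    stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-8,
                     subdivisions = 500L)$value
  } else {
    ## prior mass below zero is 1/2; truncation renormalizes by 2
    2 * stats::integrate(integrand, -Inf, 0, rel.tol = 1e-8,
                         subdivisions = 500L)$value
  }
  if (!is.finite(m1) || m1 <= 0) stop("quadrature failed to converge")
  m0 / m1
}

#' Full two-level analysis of a cohort trial table
#'
#' Fits the trial-wise regression per participant and performs the
#' second-level tests the study design prescribes: a directional
#' (negative one-sided) t-test and BF0- for the trial-number slope, and
#' two-sided t-tests and BF01 for WT, MD and PA.
#'
#' @param records Row-bound trial tables with a `participant` column.
#' @param r Cauchy prior scale for the Bayes factors.
#' @return List with `coefficients` (participants x 5 matrix) and `tests`
#'   (data frame: variable, side, t, df, p, bf).
#' @export
analyzeScores <- function(records, r = sqrt(2) / 2) {
  byP <- split(records, records$participant)
  coefs <- t(vapply(byP, fitTrialwiseRegression, numeric(5)))
  n <- nrow(coefs)
  sides <- c(tn = "negative_one_sided", wt = "two_sided",
             md = "two_sided", pa = "two_sided")
  tests <- do.call(rbind, lapply(names(sides), function(v) {
    tt <- secondLevelTTest(coefs[, v], sides[[v]])
    data.frame(variable = v, side = sides[[v]], t = tt$t, df = tt$df,
               p = tt$p, bf = jzsBayesFactor(tt$t, n, r, sides[[v]]))
  }))
  list(coefficients = coefs, tests = tests)
}

## Baseline-corrected Cz waveform of the [-1000, 0) ms window before a
## lock sample: baseline is the mean over [-1000, -900).
czWaveform <- function(eeg, tLock, channel = "Cz") {
  idx <- match(channel, channelLabels(eeg))
  if (is.na(idx)) stop("channel ", channel, " not present")
  seg <- sliceSegment(eeg, tLock, c(-1000, 0))[idx, ]
  seg - mean(seg[seq_len(msToSamples(100, samplingRate(eeg)))])
}

#' Single-trial RP amplitude
#'
#' Mean voltage over the final 100 ms of the baseline-corrected
#' 1000-ms window preceding each movement onset, at one channel.
#'
#' @param eeg EEG [Recording-class].
#' @param onsets 0-based movement-onset samples.
#' @param channel Channel label (default `"Cz"`).
#' @return Numeric vector of amplitudes (uV), one per onset.
#' @export
singleTrialAmplitude <- function(eeg, onsets, channel = "Cz") {
  fs <- samplingRate(eeg)
  w <- msToSamples(100, fs)
  vapply(onsets, function(t) {
    wf <- czWaveform(eeg, t, channel)
    mean(wf[(length(wf) - w + 1L):length(wf)])
  }, 0)
}

## Balanced group assignment by stable rank: ties are broken by trial
## order, group g of k gets floor((rank-1) * k / n) + 1.
rankGroups <- function(x, k) {
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * k / length(x)) + 1L)
}

#' Score-quintile RP waveforms
#'
#' Per participant, kept trials are split into five quintiles by feedback
#' score (stable rank order; ties broken by trial order), the
#' baseline-corrected Cz waveforms over \[-1000, 0) ms before onset are
#' averaged per quintile, and quintile averages are grand-averaged across
#' participants. The summary amplitude is the mean voltage over
#' \[-100, 0) ms per quintile.
#'
#' @param sessions List, one element per participant, each a list with
#'   `eeg` ([Recording-class]) and `records` (trial table with
#'   `onset_sample`, `score`, and optionally `excluded`).
#' @param channel Channel label (default `"Cz"`).
#' @return List with `waveforms` (5 x window-length matrix), `amplitude`
#'   (length-5 vector, quintile 1 = lowest scores) and `timeMs`.
#' @export
quintileWaveforms <- function(sessions, channel = "Cz") {
  fs <- samplingRate(sessions[[1L]]$eeg)
  len <- msToSamples(1000, fs)
  w100 <- msToSamples(100, fs)
  perP <- lapply(sessions, function(s) {
    rec <- s$records
    if (!is.null(rec$excluded)) rec <- rec[!rec$excluded, ]
    if (nrow(rec) < 5L) stop("need at least 5 kept trials per participant")
    g <- rankGroups(rec$score, 5L)
    t(vapply(1:5, function(q) {
      locks <- rec$onset_sample[g == q]
      rowMeans(vapply(locks, czWaveform, numeric(len), eeg = s$eeg,
                      channel = channel))
    }, numeric(len)))
  })
  grand <- Reduce(`+`, perP) / length(perP)
  list(waveforms = grand,
       amplitude = rowMeans(grand[, (len - w100 + 1L):len, drop = FALSE]),
       timeMs = (seq_len(len) - 0.5) * 1000 / len - 1000)
}

#' Score-amplitude relation
#'
#' Regression of the feedback score on the single-trial RP amplitude
#' with participant-specific intercepts, fitted by within-participant
#' centering of both variables (the fixed-effects estimator; equivalent
#' to a random-intercept model for the slope). The slope is in score
#' units per microvolt.
#'
#' @param scores,amplitudes,participants Parallel per-trial vectors
#'   across the cohort (>= 2 participants, >= 10 trials each).
#' @return List with `slope`, `se`, `t`, `df` and `p`.
#' @export
scoreAmplitudeModel <- function(scores, amplitudes, participants) {
  byP <- split(seq_along(scores), participants)
  if (length(byP) < 2L || any(lengths(byP) < 10L))
    stop("need >= 2 participants with >= 10 trials each")
  center <- function(v) {
    for (idx in byP) v[idx] <- v[idx] - mean(v[idx])
    v
  }
  yc <- center(scores); xc <- center(amplitudes)
  sxx <- sum(xc^2)
  if (sxx <= .Machine$double.eps * length(xc))
    stop("degenerate amplitude variance")
  slope <- sum(xc * yc) / sxx
  df <- length(yc) - length(byP) - 1L
  se <- sqrt(sum((yc - slope * xc)^2) / df / sxx)
  t <- slope / se
  list(slope = slope, se = se, t = t, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

#' Median-split RP waveforms by a movement characteristic
#'
#' Per participant, kept trials are split at the median of a movement
#' characteristic (WT, MD or PA; with an odd trial count the median trial
#' goes to the lower half), Cz waveforms are averaged per half and
#' grand-averaged across participants, and each of the ten consecutive
#' 100-ms windows is tested with a paired t-test across participants at
#' alpha = 0.05, uncorrected.
#'
#' @param sessions As in [quintileWaveforms()]; `records` must contain
#'   the split variable.
#' @param variable One of `"wt_s"`, `"md_s"`, `"pa"`.
#' @param channel Channel label.
#' @return List with `low`, `high` (grand-average waveforms), `windows`
#'   (data frame: window, tStat, p, significant) and `timeMs`.
#' @export
medianSplitWaveforms <- function(sessions, variable = c("wt_s", "md_s", "pa"),
                                 channel = "Cz") {
  variable <- match.arg(variable)
  fs <- samplingRate(sessions[[1L]]$eeg)
  len <- msToSamples(1000, fs)
  binLen <- len %/% 10L
  perP <- lapply(sessions, function(s) {
    rec <- s$records
    if (!is.null(rec$excluded)) rec <- rec[!rec$excluded, ]
    if (nrow(rec) < 8L) stop("need at least 4 trials per half")
    lower <- rank(rec[[variable]], ties.method = "first") <=
      ceiling(nrow(rec) / 2)
    avg <- function(locks)
      rowMeans(vapply(locks, czWaveform, numeric(len), eeg = s$eeg,
                      channel = channel))
    rbind(low = avg(rec$onset_sample[lower]),
          high = avg(rec$onset_sample[!lower]))
  })
  bin <- rep(1:10, each = binLen)
  binMeans <- function(w) tapply(w, bin, mean)
  lowBins <- t(vapply(perP, function(m) binMeans(m["low", ]), numeric(10)))
  highBins <- t(vapply(perP, function(m) binMeans(m["high", ]), numeric(10)))
  tests <- do.call(rbind, lapply(1:10, function(k) {
    ## the baseline window is identically zero after correction (up to
    ## rounding); its paired test is undefined and reported as NA
    diffs <- lowBins[, k] - highBins[, k]
    degenerate <- stats::sd(diffs) <=
      1e-9 * max(abs(c(lowBins, highBins)), 1e-300)
    tt <- if (degenerate) NULL else
      tryCatch(stats::t.test(lowBins[, k], highBins[, k], paired = TRUE),
               error = function(e) NULL)
    data.frame(window = k,
               tStat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  }))
  tests$significant <- !is.na(tests$p) & tests$p < 0.05
  grand <- Reduce(`+`, perP) / length(perP)
  list(low = grand["low", ], high = grand["high", ], windows = tests,
       timeMs = (seq_len(len) - 0.5) * 1000 / len - 1000)
}
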