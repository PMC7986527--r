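#' Default 51-channel EEG montage
#'
#' The extended 10-20 labels used by default in simulated sessions. The
#' montage holds 51 unique labels covering frontal to occipital rows with
#' the vertex (Cz) present.
#'
#' @return Character vector of 51 channel labels.
#' @export
defaultMontage <- function() {
  c("AF7", "AF3", "Fpz", "AF4", "AF8", "FT7", "F5", "F3", "F1", "Fz",
    "F2", "F4", "F6", "FT8", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "CP5", "CP3", "CP1",
    "CPz", "CP2", "CP4", "CP6", "TP7", "P5", "P3", "P1", "Pz", "P2",
    "P4", "P6", "TP8", "PO3", "PO1", "POz", "PO2", "PO4", "O1", "Oz",
    "O2")
}

#' Planar 10-20 channel coordinates
#'
#' Idealized 2-D positions for standard 10-20 labels, used to weight the
#' simulated RP topography by distance from the vertex. Rows map to the
#' anterior-posterior axis, digits to laterality (odd left, even right).
#'
#' @param labels Character vector of channel labels.
#' @return Numeric matrix with columns `x`, `y`, rownames = labels.
#' @export
channelPositions <- function(labels) {
  rowY <- c(Fp = 0.8, AF = 0.6, F = 0.4, FT = 0.2, FC = 0.2, C = 0,
            T = 0, CP = -0.2, TP = -0.2, P = -0.4, PO = -0.6, O = -0.8,
            I = -0.9)
  m <- regmatches(labels, regexec("^(Fp|AF|FT|FC|F|CP|TP|C|T|PO|P|O|I)(z|[0-9]+)$",
                                  labels))
  bad <- lengths(m) == 0L
  if (any(bad))
    stop("unrecognized channel label(s): ", paste(labels[bad], collapse = ", "))
  row <- vapply(m, `[`, "", 2L)
  num <- vapply(m, `[`, "", 3L)
  y <- unname(rowY[row])
  x <- ifelse(num == "z", 0, {
    n <- suppressWarnings(as.integer(num))
    ifelse(n %% 2L == 1L, -1, 1) * 0.2 * ceiling(n / 2)
  })
  out <- cbind(x = x, y = y)
  rownames(out) <- labels
  out
}

#' Simulation configuration
#'
#' Parameters of a synthetic single-participant session. Defaults emulate
#' the study conditions of a self-paced pedal-press neurofeedback
#' experiment: 1-kHz EEG on a 51-channel montage, a negative-going vertex
#' ramp ("RP") ending at movement onset, pink + white background noise,
#' an instructed ~2-s waiting period, and brief high-variance
#' accelerometer bursts between movement onset and pedal press.
#'
#' @slot nTrials Number of trials (preparatory stage default 100).
#' @slot fs Sampling rate, Hz.
#' @slot labels EEG channel labels.
#' @slot rpLeadMs RP ramp duration before movement onset, ms.
#' @slot rpAmpUv Mean peak RP negativity at Cz, microvolts (>= 0).
#' @slot topoSigma Gaussian falloff width of the topography, in planar
#'   montage distance units from Cz.
#' @slot noisePinkUv,noiseWhiteUv SDs of the 1/f and white EEG noise, uV.
#' @slot wtMeanS,wtSdS Waiting time (cue to onset) mean / SD, seconds.
#' @slot mdMeanS,mdSdS Movement duration (onset to press) mean / SD, s.
#' @slot paMean,paSd Peak acceleration of the burst, device units.
#' @slot accelNoiseSd Accelerometer baseline noise SD, device units.
#' @slot burstRiseMs Attack time of the burst envelope, ms: the envelope
#'   rises as a quarter-sine over this interval, sustains, and releases
#'   as a quarter-sine over its final 100 ms.
#' @slot burstDir Mean direction (3-vector, any norm) of the movement
#'   burst in device coordinates: the accelerometer sits in a fixed
#'   position on the calf, so the burst orientation is a property of the
#'   setup and is shared by the preparatory and feedback stages. Each
#'   trial wobbles around it.
#' @slot ampJitterSdLog SD (log scale) of the multiplicative lognormal
#'   per-trial RP amplitude jitter (unit mean).
#' @slot effectBetas Named numeric `c(tn=, wt=, md=, pa=)`: linear effects
#'   of the (centered) trial covariates on per-trial RP amplitude, uV per
#'   covariate unit.
#' @slot leadInS,itiS,postPressS Recording lead-in, intertrial interval
#'   and post-press interval, seconds.
#' @slot seed RNG seed for reproducibility.
#'
#' @seealso [simConfig()], [simulateParticipant()]
#' @export
setClass("SimConfig",
  representation(nTrials = "integer", fs = "numeric", labels = "character",
    rpLeadMs = "numeric", rpAmpUv = "numeric", topoSigma = "numeric",
    noisePinkUv = "numeric", noiseWhiteUv = "numeric",
    wtMeanS = "numeric", wtSdS = "numeric", mdMeanS = "numeric",
    mdSdS = "numeric", paMean = "numeric", paSd = "numeric",
    accelNoiseSd = "numeric", burstRiseMs = "numeric",
    burstDir = "numeric", ampJitterSdLog = "numeric",
    effectBetas = "numeric", leadInS = "numeric", itiS = "numeric",
    postPressS = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    sds <- c(object@wtSdS, object@mdSdS, object@paSd, object@accelNoiseSd,
             object@noisePinkUv, object@noiseWhiteUv, object@ampJitterSdLog)
    if (any(sds < 0)) msg <- c(msg, "all SDs must be >= 0")
    if (object@rpAmpUv < 0) msg <- c(msg, "rpAmpUv must be >= 0")
    if (object@rpLeadMs <= 0) msg <- c(msg, "rpLeadMs must be > 0")
    if (object@burstRiseMs <= 0) msg <- c(msg, "burstRiseMs must be > 0")
    if (length(object@burstDir) != 3L || sum(object@burstDir^2) == 0)
      msg <- c(msg, "burstDir must be a non-zero 3-vector")
    labelCheck <- tryCatch({ channelPositions(object@labels); NULL },
                           error = function(e) conditionMessage(e))
    if (!is.null(labelCheck)) msg <- c(msg, labelCheck)
    if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
    if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
    if (object@wtMeanS < 1.0)
      msg <- c(msg, "wtMeanS must be >= 1.0 (instructed ~2-s wait)")
    if (!all(c("tn", "wt", "md", "pa") %in% names(object@effectBetas)))
      msg <- c(msg, "effectBetas must be named tn, wt, md, pa")
    if (object@leadInS * 1000 < object@rpLeadMs)
      msg <- c(msg, "leadInS must cover at least the RP lead")
    if (length(msg)) msg else TRUE
  }
)

#' Create a simulation configuration
#'
#' @param nTrials,fs,labels,rpLeadMs,rpAmpUv,topoSigma See
#'   [SimConfig-class].
#' @param noisePinkUv,noiseWhiteUv,wtMeanS,wtSdS,mdMeanS,mdSdS See
#'   [SimConfig-class].
#' @param paMean,paSd,accelNoiseSd,burstRiseMs,burstDir See
#'   [SimConfig-class].
#' @param ampJitterSdLog,effectBetas See
#'   [SimConfig-class].
#' @param leadInS,itiS,postPressS,seed See [SimConfig-class].
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nTrials = 5, fs = 200, labels = c("Cz", "C1", "Fz"))
#' @export
simConfig <- function(nTrials = 100L, fs = 1000, labels = defaultMontage(),
                      rpLeadMs = 1000, rpAmpUv = 8, topoSigma = 0.45,
                      noisePinkUv = 6, noiseWhiteUv = 2,
                      wtMeanS = 2.5, wtSdS = 0.5,
                      mdMeanS = 0.3, mdSdS = 0.08,
                      paMean = 10, paSd = 2, accelNoiseSd = 1,
                      burstRiseMs = 10, burstDir = c(2, 1, 1),
                      ampJitterSdLog = 0.3,
                      effectBetas = c(tn = 0, wt = 0, md = 0, pa = 0),
                      leadInS = 2, itiS = 3, postPressS = 1.5,
                      seed = 1L) {
  new("SimConfig", nTrials = as.integer(nTrials), fs = fs, labels = labels,
      rpLeadMs = rpLeadMs, rpAmpUv = rpAmpUv, topoSigma = topoSigma,
      noisePinkUv = noisePinkUv, noiseWhiteUv = noiseWhiteUv,
      wtMeanS = wtMeanS, wtSdS = wtSdS, mdMeanS = mdMeanS, mdSdS = mdSdS,
      paMean = paMean, paSd = paSd, accelNoiseSd = accelNoiseSd,
      burstRiseMs = burstRiseMs, burstDir = burstDir,
      ampJitterSdLog = ampJitterSdLog,
      effectBetas = effectBetas,
      leadInS = leadInS, itiS = itiS, postPressS = postPressS,
      seed = as.integer(seed))
}

#' Linear readiness-potential template
#'
#' The simulated RP is the continuous line dropping from 0 to `-ampUv`
#' over `leadMs` milliseconds, sampled at sample centers so that means
#' over sub-windows equal the continuous-line means exactly (e.g. the
#' mean over the final 100 ms equals `-ampUv * (1 - 50 / leadMs)`).
#'
#' @param leadMs Ramp duration in ms (> 0).
#' @param ampUv Peak negativity in microvolts at the end of the ramp.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `leadMs * fs / 1000` samples from ~0 down to
#'   ~`-ampUv`.
#' @examples
#' w <- rpTemplate(1000, 10, 1000)
#' w[500]  # approximately -5 uV at the ramp midpoint
#' @export
rpTemplate <- function(leadMs, ampUv, fs) {
  if (leadMs <= 0 || fs <= 0) stop("leadMs and fs must be positive")
  n <- msToSamples(leadMs, fs)
  -ampUv * (seq_len(n) - 0.5) / n
}

#' 1/f ("pink") noise
#'
#' Spectrally shaped white noise: the discrete spectrum of a white draw is
#' scaled by `1/sqrt(f)` (DC removed) and inverted, then normalized to
#' unit SD. Produces the slow drifts that stress baseline correction and
#' channel selection.
#'
#' @param n Number of samples.
#' @return Numeric vector of length `n` with SD 1.
#' @export
pinkNoise <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5))  # keep the FFT fast at any length
  w <- stats::rnorm(m)
  spec <- stats::fft(w)
  k <- seq_len(m) - 1
  f <- pmin(k, m - k)
  scale <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::fft(spec * scale, inverse = TRUE))[seq_len(n)] / m
  x / popSd(x)
}

truncNorm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate one participant session
#'
#' Generates a full session with known ground truth: a cue (trial start)
#' per trial, a movement onset drawn `WT` seconds later, a pedal press
#' `MD` seconds after onset, an RP ramp ending at onset (held at its peak
#' until the press as a motor-potential continuation, then released over
#' 300 ms) projected over the montage with Gaussian falloff from Cz,
#' pink + white EEG noise, and an accelerometer burst (a unit-variance
#' broadband carrier under a fast-attack / sustained /
#' quarter-sine-release envelope, scaled so its sustained RMS amplitude
#' equals the PA draw) between onset and press on top of Gaussian
#' baseline noise. `paMean / accelNoiseSd` is therefore the burst
#' signal-to-noise ratio seen by the variance-based onset detector.
#'
#' Per-trial RP amplitude is
#' `max(0, (rpAmpUv + sum(effectBetas * centered covariates)) * jitter)`
#' with unit-mean lognormal jitter; covariates (TN, WT, MD, PA) are
#' centered at their configured means so that `rpAmpUv` stays the mean
#' amplitude.
#'
#' @param config A [SimConfig-class].
#' @return List with `eeg` ([Recording-class], uV), `accel`
#'   ([Recording-class], device units, channels accX/accY/accZ), `events`
#'   ([EventList-class]) and `truth` (data frame with `trial`,
#'   `true_onset_sample`, `true_rp_amplitude_uv`, `wt_s`, `md_s`, `pa`).
#'   Deterministic given `config@seed`.
#' @examples
#' sess <- simulateParticipant(simConfig(nTrials = 3, fs = 200,
#'   labels = c("Cz", "C1", "Fz")))
#' nTrials(sess$events)
#' @export
simulateParticipant <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    fs <- config@fs
    n <- config@nTrials
    wt <- truncNorm(n, config@wtMeanS, config@wtSdS, lower = 0.3)
    md <- truncNorm(n, config@mdMeanS, config@mdSdS, lower = 0.05)
    pa <- truncNorm(n, config@paMean, config@paSd, lower = 0.1)
    tn <- seq_len(n)

    b <- config@effectBetas
    cov <- cbind(tn - (n + 1) / 2, wt - config@wtMeanS,
                 md - config@mdMeanS, pa - config@paMean)
    jitter <- stats::rlnorm(n, -config@ampJitterSdLog^2 / 2,
                            config@ampJitterSdLog)
    amp <- pmax(0, (config@rpAmpUv +
                      cov %*% b[c("tn", "wt", "md", "pa")]) * jitter)
    amp <- as.vector(amp)

    start <- integer(n); onset <- integer(n); press <- integer(n)
    cur <- round(config@leadInS * fs)
    gap <- round((config@postPressS + config@itiS) * fs)
    for (i in seq_len(n)) {
      start[i] <- cur
      onset[i] <- start[i] + round(wt[i] * fs)
      press[i] <- onset[i] + round(md[i] * fs)
      cur <- press[i] + gap
    }
    total <- cur + round(fs)

    ## vertex source signal: ramp into onset, plateau to press, release
    src <- numeric(total)
    lead <- msToSamples(config@rpLeadMs, fs)
    release <- msToSamples(300, fs)
    for (i in seq_len(n)) {
      ramp <- -amp[i] * (seq_len(lead) - 0.5) / lead
      i0 <- onset[i] - lead            # 0-based start of ramp
      idx <- (i0 + 1L):onset[i]        # 1-based matrix columns
      keep <- idx >= 1L
      src[idx[keep]] <- src[idx[keep]] + ramp[keep]
      if (press[i] > onset[i])
        src[(onset[i] + 1L):press[i]] <- src[(onset[i] + 1L):press[i]] - amp[i]
      rel <- -amp[i] * (1 - (seq_len(release) - 0.5) / release)
      ridx <- (press[i] + 1L):(press[i] + release)
      keep <- ridx <= total
      src[ridx[keep]] <- src[ridx[keep]] + rel[keep]
    }

    pos <- channelPositions(config@labels)
    d2 <- pos[, "x"]^2 + pos[, "y"]^2  # distance^2 from Cz at the origin
    gain <- exp(-d2 / (2 * config@topoSigma^2))

    nch <- length(config@labels)
    eeg <- matrix(0, nch, total)
    for (ch in seq_len(nch)) {
      noise <- 0
      if (config@noisePinkUv > 0)
        noise <- noise + config@noisePinkUv * pinkNoise(total)
      if (config@noiseWhiteUv > 0)
        noise <- noise + stats::rnorm(total, sd = config@noiseWhiteUv)
      eeg[ch, ] <- gain[ch] * src + noise
    }

    acc <- matrix(stats::rnorm(3 * total, sd = config@accelNoiseSd), 3, total)
    rise <- max(1L, msToSamples(config@burstRiseMs, fs))
    ## limb orientation is a fixed property of the setup, with wobble
    dir0 <- config@burstDir / sqrt(sum(config@burstDir^2))
    for (i in seq_len(n)) {
      bLen <- press[i] - onset[i]
      if (bLen < 1L) next
      dir <- dir0 + 0.2 * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      ## fast quarter-sine attack, sustain, quarter-sine release: limb
      ## acceleration rises abruptly at jerk onset
      t <- seq_len(bLen) - 0.5
      release <- max(1L, min(bLen %/% 2L, msToSamples(100, fs)))
      env <- pmin(sin(pi * pmin(t, rise) / (2 * rise)),
                  sin(pi * pmax(0, pmin(bLen - t, release)) / (2 * release)))
      carrier <- stats::rnorm(bLen)
      raw <- env * (carrier / popSd(carrier))
      acc[, (onset[i] + 1L):press[i]] <-
        acc[, (onset[i] + 1L):press[i]] + pa[i] * outer(dir, raw)
    }

    list(
      eeg = Recording(eeg, fs, config@labels),
      accel = Recording(acc, fs, c("accX", "accY", "accZ")),
      events = EventList(start, press),
      truth = data.frame(trial = tn, true_onset_sample = onset,
                         true_rp_amplitude_uv = amp,
                         wt_s = wt, md_s = md, pa = pa)
    )
  })
}

#' Simulate a cohort of participants
#'
#' Draws one independent session per participant, with per-participant
#' seeds derived reproducibly from the master seed in `config@seed`.
#'
#' @param nParticipants Number of participants (>= 1).
#' @param config A [SimConfig-class]; its `seed` acts as the master seed.
#' @return List of length `nParticipants` of [simulateParticipant()]
#'   results.
#' @export
simulateCohort <- function(nParticipants, config) {
  stopifnot(nParticipants >= 1)
  seeds <- withSeed(config@seed,
                    sample.int(.Machine$integer.max - 1L, nParticipants))
  lapply(seeds, function(s) {
    cfg <- config
    cfg@seed <- s
    simulateParticipant(cfg)
  })
}

#' Simulate a cohort at the feedback-score level
#'
#' Generates per-trial feedback scores and movement covariates directly,
#' bypassing signal synthesis, for studying the two-level inference:
#' `score = 50 + betaTn * z(TN) + betaWt * z(WT) + betaMd * z(MD) +
#' betaPa * z(PA) + noise`, rounded to an integer. Per-participant slopes
#' vary around the nominal betas with SD `betweenSd`.
#'
#' @param nParticipants Participants per cohort (default 19).
#' @param nTrialsEach Kept trials per participant (default 250).
#' @param betaTn,betaWt,betaMd,betaPa Population mean slopes in score
#'   units per z-scored covariate.
#' @param betweenSd Between-participant SD of each slope.
#' @param scoreNoiseSd Residual score SD within participant.
#' @param seed RNG seed.
#' @return Data frame with `participant`, `trial`, `wt_s`, `md_s`, `pa`,
#'   `score`, `excluded` (all `FALSE`).
#' @export
simulateScoreCohort <- function(nParticipants = 19, nTrialsEach = 250,
                                betaTn = 0, betaWt = 0, betaMd = 0,
                                betaPa = 0, betweenSd = 0.1,
                                scoreNoiseSd = 7, seed = 1L) {
  withSeed(seed, {
    out <- lapply(seq_len(nParticipants), function(p) {
      tn <- seq_len(nTrialsEach)
      wt <- truncNorm(nTrialsEach, 2.5, 0.5, 0.3)
      md <- truncNorm(nTrialsEach, 0.3, 0.08, 0.05)
      pa <- truncNorm(nTrialsEach, 10, 2, 0.1)
      z <- function(x) (x - mean(x)) / stats::sd(x)
      slopes <- stats::rnorm(4, c(betaTn, betaWt, betaMd, betaPa), betweenSd)
      score <- 50 + slopes[1] * z(tn) + slopes[2] * z(wt) +
        slopes[3] * z(md) + slopes[4] * z(pa) +
        stats::rnorm(nTrialsEach, sd = scoreNoiseSd)
      data.frame(participant = sprintf("P%02d", p), trial = tn,
                 wt_s = wt, md_s = md, pa = pa,
                 score = as.integer(roundHalfAway(score)),
                 excluded = FALSE)
    })
    do.call(rbind, out)
  })
}
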