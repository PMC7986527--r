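---
title: "Methods: single-trial readiness-potential scoring and closed-loop replay"
author: "rpfeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial readiness-potential scoring and closed-loop replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpfeedback)
```

# The scientific problem

The readiness potential (RP, Bereitschaftspotential) is a slow negative
EEG deflection over motor cortex that builds up for roughly a second
before self-initiated movements, maximal at the vertex (Cz) for foot
movements. A closed-loop neurofeedback design asks whether people can
willfully suppress it: participants perform self-paced pedal presses, a
classifier scores the RP of each movement in real time, and the score is
fed back after every trial. The inferential question — did scores drift
down over trials? — is answered at two levels, with frequentist t-tests
and with Bayes factors that can quantify evidence *for* the null.

`rpfeedback` implements that entire measurement and analysis chain as
reusable, tested components, together with a synthetic generator that
produces sessions with known ground truth so every stage can be
validated without human recordings.

# Pipeline overview

A session has two stages. The **preparatory stage** (100 trials by
convention) yields training data:

1. **Movement-onset detection.** A linear discriminant (LDA, pooled
   covariance, equal priors) on per-axis log-variance features
   `ln(var + 1e-12)` of 200-ms accelerometer windows separates
   "movement" (the 200 ms before the pedal press) from "idle" (300–500
   ms after the cue). Onsets are found by sliding a window backward,
   sample by sample, from the press until the classifier first reports
   idle; the *end* of that window is the registered onset. Onsets are
   estimated per trial by leave-one-out, and trials whose onset-to-press
   latency is more than 3 population SDs from the participant mean are
   excluded in a single pass.
2. **Channel selection.** Per channel, the segment-change statistic
   Δ = mean(last 200 ms) − mean(first 200 ms) of the 1000-ms segment
   preceding each movement onset is tested one-sided against zero, and
   (paired, per trial) against the same statistic before the trial-start
   cue. A channel is kept iff both tests reject at α = 0.05.
3. **RP classifier and calibration.** Segments preceding onset and cue
   are baseline-corrected to the mean of their first 100 ms and averaged
   in ten consecutive 100-ms bins, concatenated over selected channels.
   A shrinkage-regularized LDA (pooled covariance shrunk toward
   `nu * I`, `nu = mean(diag(S))`, with the analytic Ledoit–Wolf
   intensity clamped to [0, 1]) separates the two classes. Leave-one-out
   outputs on the onset segments give the calibration (μ₀, σ₀), and a
   classifier output x maps to the integer feedback score
   `round(((x − μ₀)/σ₀)·15 + 50)` — 50 for an average RP, 65/35 at ±1 SD.

The **feedback stage** (300 trials by convention) is replayed causally:
both classifiers are evaluated on a 20-ms grid of window-end times; at
each press the accelerometer outputs are scanned backward along the grid
to the latest grid point classified idle (the online onset), and the
score is the EEG output whose 1000-ms window ends there. Trials are then
excluded as *multiphasic* (summed-axis accelerometer variance in the
second before the assigned onset above `mean + 3·SD` of the preparatory
resting baseline) or *premature* (waiting time strictly below 1000 ms),
and participants with strictly more than 50% excluded trials are
dropped.

**Inference** is two-level: per participant, ordinary least squares of
the scores on z-scored trial number (TN), waiting time (WT), movement
duration (MD) and peak acceleration (PA) plus a constant; across
participants, one-sample t-tests on each coefficient (one-sided negative
for TN, two-sided otherwise) and JZS Bayes factors with a Cauchy(0,
√2/2) prior on the standardized effect, truncated to negative effects
for the directional test. The Bayes factor is computed as the ratio of
the central-t density at the observed statistic to the marginal
likelihood under the prior, by adaptive quadrature (relative tolerance
1e-8); the directional prior is renormalized by 2 on the negative half
line.

```{r bf}
jzsBayesFactor(0.103, n = 19, side = "negative_one_sided")
jzsBayesFactor(-1.121, n = 19, side = "two_sided")
```

# The synthetic generator

`simulateParticipant()` draws, per trial, a waiting time (default
N(2.5 s, 0.5 s), truncated at 0.3 s — the task instructs an
approximately 2-s wait), a movement duration (N(0.3 s, 0.08 s)) and a
peak acceleration, then renders:

* an **RP**: a linear ramp from 0 down to the trial's amplitude, ending
  at the true onset, held at its peak until the press (a motor-potential
  continuation) and released over 300 ms. The ramp is the continuous
  line sampled at sample centers, so windowed means are exact: with
  zero noise the mean over the final 100 ms equals
  `-amp * (1 - 50/leadMs)` to machine precision, which the tests
  exploit. Per-trial amplitude is
  `max(0, (rpAmpUv + effects) * lognormal jitter)` with unit-mean jitter;
  covariate effects (TN, WT, MD, PA) act linearly on the amplitude and
  are centered at their configured means so `rpAmpUv` remains the mean
  amplitude. This linear covariate structure is what the statistics
  module is asked to recover — it is a test harness, not a biological
  claim.
* a **topography**: Gaussian falloff of the ramp with planar 10-20
  distance from Cz (default width 0.45 montage units), motivated by the
  vertex-focal distribution of foot-movement RPs. The default montage
  has 51 unique labels; a duplicated posterior label in the published
  montage listing was replaced by PO4 so labels stay unique.
* **EEG noise**: independent per channel, 1/f ("pink", default 6 µV) via
  spectral shaping of white noise plus white noise (default 2 µV). Pink
  noise produces the slow drifts that stress baseline correction and the
  drift-guard in channel selection. The FFT length is padded to the next
  5-smooth number, so generation stays O(n log n) at any session length.
* an **accelerometer burst** from onset to press on top of Gaussian
  baseline noise: a unit-variance broadband carrier under an envelope
  with a fast quarter-sine attack (default 10 ms), sustain, and a
  quarter-sine release (≤ 100 ms), scaled so the sustained RMS equals
  the trial's PA draw. Two choices matter here. First, the attack is
  fast because limb acceleration rises abruptly at jerk onset; a slow
  symmetric envelope would make "movement onset" physically ill-defined
  at the tens-of-milliseconds scale on which the detector is validated
  (a backward search that stops at the first window without evidence is
  necessarily late by about `window length / SNR`; with a slow envelope
  that latency grows to ~100 ms). Second, scaling the *RMS* (rather
  than the peak) to PA makes `paMean/accelNoiseSd` exactly the
  signal-to-noise ratio the variance-based detector sees. Burst
  direction is a fixed property of the device placement (default
  direction (2,1,1)/√6, per-trial wobble 0.2), shared between the
  stages of a session — a per-trial random orientation would make the
  per-axis log-variance features bimodal and is unphysical.

What the generator does **not** emulate: eye blinks and EMG artifacts,
volume-conducted correlated noise, realistic head-model projection,
non-stationary waiting-time strategies, and any genuine feedback loop
from score to behavior. Passing tests therefore show that the pipeline
recovers what it is designed to recover under clean, stationary
conditions — they do not certify performance on real recordings.

`simulateScoreCohort()` generates trial tables directly at the score
level (score = 50 + slopes · z-covariates + noise, rounded) for
calibration studies of the two-level inference, where rendering full
EEG would add nothing: the first-level regression consumes only scores
and covariates. Its residual SD default of 7 score units with
between-participant slope SD 0.1 was set by an a-priori power
analysis: with 19 participants × 250 kept trials, an injected TN slope
of −0.3 then corresponds to a second-level noncentrality of ≈2.9,
i.e. ≈87% power for the one-sided test — the moderate-SNR regime in
which parameter recovery is meaningfully testable (at the full 15-unit
score SD of the calibrated transform, the same effect would have ≈39%
power and no recovery criterion could be stated).

# Numerical and design choices

* **Indexing and windows.** Samples are 0-based; all windows are
  half-open `[a, b)` in ms, converted by `floor(ms·fs/1000)`, so
  `[-1000,-900)` and `[-900,0)` concatenate exactly to `[-1000,0)`.
* **Δ orientation.** The segment change is last-minus-first, so a
  negative-going RP gives Δ < 0 and the selection tests are "smaller
  than zero"; the drift test is paired within trial.
* **Onset registration.** The backward search registers the *end* of the
  last idle window: the last instant with no evidence of movement. The
  alternatives (window start or center) would be early by constant
  offsets of the window length.
* **Degenerate cases are flagged, not errored**, where the real-time
  system had to keep running: a trial already idle at the press returns
  the press sample with `no_movement_detected`; a trial with no idle
  window back to the cue returns the trial start with `no_idle_found`;
  a score window that would begin before the recording flags the trial
  `unusable`. Exclusion rules treat all flagged trials as excluded.
* **Zero-variance features** (the first bin per channel is identically
  zero after baseline correction) are retained: ten bins per channel is
  the feature contract, and under shrinkage the pooled covariance stays
  invertible with negligible weight on constant features. Plain LDA
  falls back to a Moore–Penrose solution only when rank deficiency comes
  from very few training windows; a truly zero-variance axis is a named
  error.
* **Rounding** of scores is half away from zero; σ₀ uses the sample
  (n−1) SD — both printed anchor points are invariant to these choices.
* **Ties.** Quintile and median splits use stable rank order (ties
  broken by trial number); with an odd trial count the median trial
  joins the lower half.
* **Channel selection during calibration** is fixed once on the
  preparatory data; leave-one-out folds do not reselect channels,
  mirroring selection as a separate prior step.
* **No multiple-testing correction** is applied anywhere; the 100-ms
  window tests of the median-split comparison are deliberately
  uncorrected, as in the study design this replays.
* **The score–amplitude relation** is fitted by within-participant
  centering (fixed-effects estimator), equivalent to a random-intercept
  model for the slope; the published mixed-model specification is not
  stated precisely enough to reproduce its exact estimator, so only the
  slope's role is comparable, not its numerical value on real data.

# Problem sizes used in the tests

Unit tests run at 100–200 Hz with ~10-channel montages and 15–40 trials
per session; these sizes exercise every code path while keeping the
suite fast. The acceptance-level property checks use the sizes the
claims refer to: onset recovery on a 100-trial session at 1 kHz and
burst SNR 10; 200 score-level cohorts (19 × 250) for power; 500 null
cohorts for type-I calibration; 200 pure-noise sessions of 48 channels
for the selection null; and a six-participant EEG cohort for the
quintile validity check. The statistical checks hold with margin at
these sizes; they are choices of the package, and larger replications
only sharpen the same estimates.

# Known limitations

* BrainVision is the only supported container (binary IEEE float32,
  multiplexed), with `trial_start`/`pedal_press` stimulus markers;
  there is no EDF reader.
* The replay models the classifier cadence but not display or amplifier
  latencies; markers are assumed sample-accurate.
* The backward-search onset is structurally late by roughly
  `window/SNR` (≈20–25 ms at SNR 10); analyses that need unbiased
  absolute latencies should correct for this or operate at higher SNR.
* The generator's RP is a deterministic ramp; waveform-shape variability
  beyond amplitude and lead time is not modeled, so classifier
  performance on synthetic data is optimistic relative to real EEG.
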