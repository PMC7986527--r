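## Shared fixture builders. Sessions are generated in code at test time;
## heavier ones are cached per test file.

smallMontage <- c("Cz", "C1", "C2", "CPz", "Fz", "Pz", "F3", "F4", "O1", "O2")

## A compact but realistic session: 200 Hz, 10 channels, clear RP.
smallSessionConfig <- function(nTrials = 20, seed = 42, ...) {
  simConfig(nTrials = nTrials, fs = 200, labels = smallMontage,
            noisePinkUv = 3, noiseWhiteUv = 1.5, seed = seed, ...)
}

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

## Trained bundle + feedback replay on a fresh session from the same
## generator settings, as one cohort participant.
makeParticipant <- function(seedPrep, seedFb, nPrep = 20, nFb = 30, ...) {
  prep <- simulateParticipant(smallSessionConfig(nPrep, seed = seedPrep, ...))
  model <- trainModelBundle(prep$eeg, prep$accel, prep$events)
  fb <- simulateParticipant(smallSessionConfig(nFb, seed = seedFb, ...))
  records <- runFeedbackStage(fb$eeg, fb$accel, fb$events, model$bundle)
  records <- applyTrialExclusions(records, fb$accel, model$baselineVar)
  list(prep = prep, model = model, fb = fb, records = records)
}

## Noise-only EEG plus regularly spaced events, built directly (no
## simulator) for null-distribution checks.
noiseEegSession <- function(nChannels, nTrials, fs = 100, noiseSd = 1,
                            labels = paste0("ch", seq_len(nChannels))) {
  spacing <- 3 * fs
  starts <- (seq_len(nTrials) - 1L) * spacing + fs
  onsets <- starts + 2L * fs
  total <- max(onsets) + fs
  eeg <- Recording(matrix(rnorm(nChannels * total, sd = noiseSd),
                          nChannels), fs, labels)
  list(eeg = eeg, events = EventList(starts, onsets + 30L),
       onsets = onsets)
}
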