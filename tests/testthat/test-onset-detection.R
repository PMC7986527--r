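test_that("log-variance features match analytic values", {
  fs <- 1000
  expect_equal(logvarFeatures(matrix(1, 3, 200), fs),
               rep(log(1e-12), 3), tolerance = 1e-6)
  ## sinusoid of amplitude 2 with integer cycles: var ~ a^2/2 = 2
  t <- seq_len(200)
  s <- rbind(2 * sin(2 * pi * 10 * t / 200),
             2 * sin(2 * pi * 5 * t / 200),
             2 * sin(2 * pi * 20 * t / 200))
  expect_equal(logvarFeatures(s, fs), rep(log(2), 3), tolerance = 0.01)
  expect_error(logvarFeatures(matrix(0, 3, 100), fs), "must be 3 x 200")
  ## i.i.d. N(0, sigma^2): feature ~ 2 log sigma
  set.seed(1)
  reps <- t(vapply(1:200, function(i)
    logvarFeatures(matrix(rnorm(600, sd = 3), 3), fs), numeric(3)))
  expect_equal(mean(reps), 2 * log(3), tolerance = 0.05)
})

test_that("accelerometer LDA separates classes and is movement-oriented", {
  set.seed(2)
  mov <- replicate(20, matrix(rnorm(600, sd = 10), 3), simplify = FALSE)
  idl <- replicate(20, matrix(rnorm(600, sd = 1), 3), simplify = FALSE)
  clf <- trainAccelClassifier(mov, idl, fs = 1000)
  fm <- t(vapply(mov, logvarFeatures, numeric(3), fs = 1000))
  fi <- t(vapply(idl, logvarFeatures, numeric(3), fs = 1000))
  outM <- fm %*% clf$weights + clf$bias
  outI <- fi %*% clf$weights + clf$bias
  expect_true(all(outM > 0) && all(outI <= 0))  # 100% training accuracy

  ## identical class distributions: chance-level accuracy
  set.seed(3)
  a <- replicate(60, matrix(rnorm(600), 3), simplify = FALSE)
  b <- replicate(60, matrix(rnorm(600), 3), simplify = FALSE)
  clf2 <- trainAccelClassifier(a, b, fs = 1000)
  fa <- t(vapply(a, logvarFeatures, numeric(3), fs = 1000))
  fb <- t(vapply(b, logvarFeatures, numeric(3), fs = 1000))
  acc <- mean(c(fa %*% clf2$weights + clf2$bias > 0,
                fb %*% clf2$weights + clf2$bias <= 0))
  expect_lt(abs(acc - 0.5), 0.2)
  ## orientation convention holds even for barely separated classes
  expect_gte(mean(fa %*% clf2$weights) + clf2$bias,
             mean(fb %*% clf2$weights) + clf2$bias)

  expect_error(trainAccelClassifier(mov[1], idl, fs = 1000), "2 examples")
  const <- replicate(5, matrix(1, 3, 200), simplify = FALSE)
  expect_error(trainAccelClassifier(const, const, fs = 1000),
               "accX.*accY.*accZ|degenerate")
})

test_that("backward search localizes a clean burst and flags degeneracies", {
  fs <- 1000
  set.seed(8)
  ## training session: 6 trials of zeros with strong bursts
  total <- 30000
  acc <- matrix(0, 3, total)
  starts <- seq(1000, by = 4500, length.out = 6)
  t0 <- starts + 2000
  press <- t0 + 400
  for (i in 1:6)
    acc[, (t0[i] + 1):press[i]] <- matrix(rnorm(3 * 400, sd = 10), 3)
  rec <- Recording(acc, fs, c("accX", "accY", "accZ"))
  ev <- EventList(starts, press)
  wins <- rpfeedback:::sessionAccelWindows(rec, ev)
  clf <- trainAccelClassifier(wins$movement, wins$idle, fs)
  for (i in 1:6) {
    res <- backwardSearchOnset(rec, press[i], clf, starts[i])
    expect_true(is.na(res$flag))
    expect_lte(abs(res$onset - t0[i]), 5)
  }

  ## all-idle trace
  quiet <- Recording(matrix(0, 3, 5000), fs, c("accX", "accY", "accZ"))
  res <- backwardSearchOnset(quiet, 4000L, clf, 1000L)
  expect_identical(res$flag, "no_movement_detected")
  expect_identical(res$onset, 4000L)

  ## burst spanning the entire trial
  busy <- Recording(matrix(rnorm(3 * 5000, sd = 10), 3), fs,
                    c("accX", "accY", "accZ"))
  res <- backwardSearchOnset(busy, 4000L, clf, 1000L)
  expect_identical(res$flag, "no_idle_found")
  expect_identical(res$onset, 1000L)

  expect_error(backwardSearchOnset(quiet, 1100L, clf, 1000L),
               "at least one window")
})

test_that("detected onsets always fall between trial start and press", {
  sess <- cachedFixture("onsetSession", simulateParticipant(
    smallSessionConfig(nTrials = 25, seed = 14)))
  ons <- looOnsets(sess$accel, sess$events)
  expect_true(all(ons$onset >= trialStarts(sess$events)))
  expect_true(all(ons$onset <= pedalPresses(sess$events)))
  ## deterministic: no randomness in detection
  expect_identical(ons, looOnsets(sess$accel, sess$events))
})

test_that("leave-one-out onsets recover ground truth on synthetic data", {
  ## at twice the nominal SNR the detector is nearly unbiased
  cfg <- simConfig(nTrials = 40, fs = 500, labels = c("Cz", "C1", "C2"),
                   paMean = 20, paSd = 2, seed = 15)
  sess <- simulateParticipant(cfg)
  ons <- looOnsets(sess$accel, sess$events)
  errMs <- (ons$onset - sess$truth$true_onset_sample) * 2
  expect_lte(median(abs(errMs)), 20)
  ## at nominal SNR 10 the backward search registers slightly late
  cfg10 <- simConfig(nTrials = 40, fs = 500, labels = c("Cz", "C1", "C2"),
                     seed = 16)
  sess10 <- simulateParticipant(cfg10)
  ons10 <- looOnsets(sess10$accel, sess10$events)
  err10 <- (ons10$onset - sess10$truth$true_onset_sample) * 2
  expect_lte(median(abs(err10)), 35)
  expect_gte(mean(abs(err10) <= 50), 0.85)

  ## minimal 3-trial session runs
  mini <- simulateParticipant(smallSessionConfig(nTrials = 3, seed = 17))
  expect_identical(nrow(looOnsets(mini$accel, mini$events)), 3L)
})

test_that("the 3-SD latency outlier rule is single-pass and symmetric", {
  lat <- c(rep(300, 99), 3000)
  keep <- onsetOutlierMask(lat)
  expect_identical(which(!keep), 100L)
  ## oracle: the same rule written out directly
  m <- mean(lat); s <- sqrt(mean((lat - m)^2))
  expect_identical(keep, abs(lat - m) <= 3 * s)
  ## re-applying to the kept trials drops nothing further (single pass)
  expect_true(all(onsetOutlierMask(lat[keep])))

  expect_true(all(onsetOutlierMask(rep(250, 10))))

  sym <- c(rnorm(60, 300, 5), 3000, -2400)
  keepSym <- onsetOutlierMask(sym)
  expect_false(keepSym[61])
  expect_false(keepSym[62])
  expect_true(all(keepSym[1:60]))
})

test_that("baseline accelerometer variance matches direct recomputation", {
  sess <- cachedFixture("onsetSession", simulateParticipant(
    smallSessionConfig(nTrials = 25, seed = 14)))
  bv <- baselineAccelVariance(sess$accel, sess$events)
  v <- vapply(trialStarts(sess$events), function(s) {
    seg <- sliceSegment(sess$accel, s, c(300, 500))
    var(seg[1, ]) + var(seg[2, ]) + var(seg[3, ])
  }, 0)
  expect_equal(bv$mean, mean(v))
  expect_equal(bv$sd, sd(v))

  quiet <- Recording(matrix(1, 3, 5000), 200, c("accX", "accY", "accZ"))
  ev <- EventList(c(200L, 2000L), c(1000L, 3000L))
  bvq <- baselineAccelVariance(quiet, ev)
  expect_lt(bvq$mean, 1e-10)
  expect_lt(bvq$sd, 1e-10)
  expect_error(baselineAccelVariance(quiet, EventList(200L, 1000L)),
               "at least 2")
})
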