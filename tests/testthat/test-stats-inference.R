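test_that("trial-wise regression recovers exact and noisy coefficients", {
  set.seed(61)
  n <- 50
  d <- data.frame(trial = 1:n, wt_s = rnorm(n, 2.5, 0.5),
                  md_s = rnorm(n, 0.3, 0.08), pa = rnorm(n, 10, 2))
  z <- function(x) (x - mean(x)) / sd(x)
  d$score <- 50 + 2 * z(d$trial)
  co <- fitTrialwiseRegression(d)
  expect_equal(co, c(tn = 2, wt = 0, md = 0, pa = 0, intercept = 50),
               tolerance = 1e-10)

  ## independent normal-equations oracle on a noisy case
  d$score <- 50 + 2 * z(d$trial) - z(d$wt_s) + rnorm(n)
  co <- fitTrialwiseRegression(d)
  x <- cbind(z(d$trial), z(d$wt_s), z(d$md_s), z(d$pa), 1)
  oracle <- solve(t(x) %*% x, t(x) %*% d$score)
  expect_equal(unname(co), as.numeric(oracle), tolerance = 1e-10)

  ## constant scores
  d$score <- 42
  co <- fitTrialwiseRegression(d)
  expect_equal(unname(co), c(0, 0, 0, 0, 42), tolerance = 1e-12)

  ## collinearity is a named error
  d$md_s <- d$wt_s
  d$score <- rnorm(n)
  expect_error(fitTrialwiseRegression(d), "collinear")
  expect_error(fitTrialwiseRegression(d[1:5, ]), "at least 6")
})

test_that("excluded trials are dropped before z-scoring and fitting", {
  set.seed(62)
  n <- 40
  d <- data.frame(trial = 1:n, wt_s = rnorm(n, 2.5, 0.5),
                  md_s = rnorm(n, 0.3, 0.08), pa = rnorm(n, 10, 2),
                  score = rnorm(n, 50, 10), excluded = rep(FALSE, n))
  d$excluded[1:10] <- TRUE
  co <- fitTrialwiseRegression(d)
  expect_equal(co, fitTrialwiseRegression(d[11:40, c(1:5)]))
})

test_that("second-level t-test matches the textbook statistic", {
  r <- secondLevelTTest(c(1, -1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r <- secondLevelTTest(c(-1, -1, -1, -1.0001), side = "negative_one_sided")
  expect_lt(r$p, 1e-3)

  set.seed(63)
  x <- rnorm(19, -0.1, 0.5)
  r2 <- secondLevelTTest(x, "two_sided")
  tt <- t.test(x)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  r1 <- secondLevelTTest(x, "negative_one_sided")
  expect_equal(r1$p, t.test(x, alternative = "less")$p.value,
               tolerance = 1e-12)
  expect_error(secondLevelTTest(rep(1, 5)), "zero variance")
})

test_that("JZS Bayes factor matches a dense-grid quadrature oracle", {
  bruteForce <- function(t, n, r = sqrt(2) / 2, side = "two_sided") {
    delta <- if (side == "two_sided") seq(-10, 10, length.out = 1e5)
             else seq(-10, 0, length.out = 1e5)
    h <- delta[2] - delta[1]
    w <- suppressWarnings(dt(t, n - 1, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, r)
    m1 <- sum(w) * h * if (side == "two_sided") 1 else 2
    dt(t, n - 1) / m1
  }
  for (case in list(list(t = 0.103, side = "negative_one_sided"),
                    list(t = -1.121, side = "two_sided"),
                    list(t = 2.4, side = "two_sided"),
                    list(t = -0.8, side = "negative_one_sided"))) {
    expect_equal(jzsBayesFactor(case$t, 19, side = case$side),
                 bruteForce(case$t, 19, side = case$side),
                 tolerance = 1e-3)
  }
})

test_that("JZS Bayes factor is symmetric, monotone and side-aware", {
  expect_equal(jzsBayesFactor(1.3, 19), jzsBayesFactor(-1.3, 19),
               tolerance = 1e-9)
  ts <- seq(-2, 2, by = 0.5)
  bfNeg <- vapply(ts, jzsBayesFactor, 0, n = 19,
                  side = "negative_one_sided")
  expect_true(all(diff(bfNeg) > 0))   # larger t: more evidence against delta<0
  tAbs <- seq(0, 3, by = 0.5)
  bf01 <- vapply(tAbs, jzsBayesFactor, 0, n = 19)
  expect_true(all(diff(bf01) < 0))
})

test_that("cohort analysis ties the levels together", {
  d <- simulateScoreCohort(nParticipants = 8, nTrialsEach = 120,
                           betaWt = -1.5, betweenSd = 0.05,
                           scoreNoiseSd = 3, seed = 64)
  a <- analyzeScores(d)
  expect_identical(dim(a$coefficients), c(8L, 5L))
  wt <- a$tests[a$tests$variable == "wt", ]
  expect_lt(wt$p, 0.01)
  expect_lt(wt$bf, 1)   # strong effect: data favor the alternative
  tn <- a$tests[a$tests$variable == "tn", ]
  expect_identical(tn$side, "negative_one_sided")
  expect_identical(tn$df, 7L)
})

test_that("quintile assignment is balanced with a stable tie rule", {
  sess <- noiseEegSession(1, 25, labels = "Cz")
  rec <- data.frame(onset_sample = sess$onsets, score = rep(50L, 25))
  q <- quintileWaveforms(list(list(eeg = sess$eeg, records = rec)))
  expect_identical(dim(q$waveforms), c(5L, 100L))
  ## ties broken by trial order: internal grouping is 5 per quintile
  g <- rpfeedback:::rankGroups(rec$score, 5L)
  expect_identical(as.integer(table(g)), rep(5L, 5))
  expect_identical(g[1:5], rep(1L, 5))
  ## baseline identity: first 100-ms bin of every quintile average ~ 0
  expect_lt(max(abs(rowMeans(q$waveforms[, 1:10]))), 1e-12)
})

test_that("score-amplitude model recovers a known slope", {
  set.seed(65)
  sim <- do.call(rbind, lapply(1:4, function(p) {
    amp <- rnorm(60, -4 - p, 2)
    data.frame(participant = p, amp = amp,
               score = 30 + 5 * p - 1.5 * amp + rnorm(60, sd = 0.8))
  }))
  fit <- scoreAmplitudeModel(sim$score, sim$amp, sim$participant)
  expect_equal(fit$slope, -1.5, tolerance = 0.2)
  expect_lt(fit$p, 0.001)

  ## amplitude-independent scores: slope ~ 0
  sim$score <- rnorm(nrow(sim), 50, 2)
  fit0 <- scoreAmplitudeModel(sim$score, sim$amp, sim$participant)
  expect_lt(abs(fit0$slope), 0.2)
  expect_identical(fit0,
                   scoreAmplitudeModel(sim$score, sim$amp, sim$participant))

  expect_error(scoreAmplitudeModel(1:20, rep(1, 20), rep(1:2, each = 10)),
               "degenerate amplitude")
})

test_that("median-split window tests are calibrated under the null", {
  set.seed(66)
  rejections <- 0L; tested <- 0L
  for (rep in 1:40) {
    sessions <- lapply(1:6, function(p) {
      s <- noiseEegSession(1, 16, labels = "Cz")
      list(eeg = s$eeg,
           records = data.frame(onset_sample = s$onsets,
                                wt_s = runif(16, 1, 4)))
    })
    w <- medianSplitWaveforms(sessions, "wt_s")$windows
    rejections <- rejections + sum(w$significant)
    tested <- tested + sum(!is.na(w$p))
  }
  rate <- rejections / tested
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)
})

test_that("an injected WT effect appears in late windows with the median trial in the lower half", {
  fs <- 100
  set.seed(67)
  sessions <- lapply(1:6, function(p) {
    s <- noiseEegSession(1, 16, fs = fs, noiseSd = 0.5, labels = "Cz")
    d <- signalData(s$eeg)
    wt <- runif(16, 1, 4)
    ramp <- rpTemplate(1000, 5, fs)
    for (i in seq_len(16)) {
      t <- s$onsets[i]
      d[1, (t - 100 + 1):t] <- d[1, (t - 100 + 1):t] + ramp * (wt[i] - 2.5)
    }
    list(eeg = Recording(d, fs, "Cz"),
         records = data.frame(onset_sample = s$onsets, wt_s = wt))
  })
  res <- medianSplitWaveforms(sessions, "wt_s")
  expect_true(res$windows$significant[10])
  expect_true(is.na(res$windows$p[1]))  # baseline window is degenerate

  ## odd trial count: the median-ranked trial joins the lower half
  s <- noiseEegSession(1, 9, fs = fs, noiseSd = 0, labels = "Cz")
  d <- signalData(s$eeg)
  v <- 1:9
  medianTrial <- which(rank(v) == 5)
  t <- s$onsets[medianTrial]
  d[1, (t - 100 + 1):t] <- 100
  sess <- list(list(eeg = Recording(d, fs, "Cz"),
                    records = data.frame(onset_sample = s$onsets,
                                         wt_s = v)),
               sessions[[1]])
  res <- medianSplitWaveforms(sess, "wt_s")
  expect_gt(mean(res$low[11:100]), mean(res$high[11:100]))
})
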