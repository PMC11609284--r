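# Cardiac-field-artifact estimation and subtraction.

test_that("CFA correction removes >=90% of R-locked power, both phases", {
  m <- standardMontage()
  tl <- simulateRRSeries(58.2, 53.5, 110, seed = 11, t0 = 2)
  ev <- eventTable(rPeakTimes(tl))
  eeg <- renderEeg(ev, list(CFA = defaultCfaTemplate(m, 15)), m,
                   fs = 250, durationS = max(rPeakTimes(tl)) + 3)
  p0 <- rLockedMeanSquare(eeg, 250, tl)
  est <- estimateCfa(eeg, 250, tl, nTriggers = 400, seed = 1)
  for (ph in c("both", "systole", "diastole")) {
    corr <- subtractCfa(eeg, est, tl, phase = ph)
    expect_lt(rLockedMeanSquare(corr, 250, tl) / p0, 0.10)
  }
  # the systole trigger-locked template reproduces the artifact shape
  # around its R-peaks: strongly correlated with the true template
  tLock <- est@triggerLocked$systole
  expect_false(is.null(tLock))
})

test_that("zero input gives a zero template", {
  tl <- constantTimeline(20, t0 = 2)
  eeg <- matrix(0, 4, 22 * 250, dimnames = list(letters[1:4], NULL))
  est <- estimateCfa(eeg, 250, tl, nTriggers = 100, seed = 2)
  expect_lt(max(abs(est@rLocked$systole)), 1e-12)
  expect_lt(max(abs(est@triggerLocked$diastole)), 1e-12)
})

test_that("more triggers shrink the template variance on noisy data", {
  tl <- constantTimeline(40, t0 = 2)
  varAt <- function(n, seed) {
    set.seed(seed)
    eeg <- matrix(rnorm(2 * 42 * 250), 2, 42 * 250,
                  dimnames = list(c("a", "b"), NULL))
    est <- estimateCfa(eeg, 250, tl, nTriggers = n, seed = seed)
    mean(est@rLocked$systole^2)
  }
  vSmall <- mean(vapply(1:6, function(s) varAt(60, s), 0))
  vBig <- mean(vapply(1:6, function(s) varAt(240, s), 0))
  expect_lt(vBig, vSmall)
})

test_that("subtracting from pure-noise data perturbs it only mildly", {
  tl <- constantTimeline(40, t0 = 2)
  set.seed(5)
  eeg <- matrix(rnorm(3 * 42 * 250, 0, 10), 3, 42 * 250,
                dimnames = list(letters[1:3], NULL))
  est <- estimateCfa(eeg, 250, tl, nTriggers = 200, seed = 5)
  corr <- subtractCfa(eeg, est, tl)
  # the subtracted template is itself noise-level: bounded perturbation
  expect_lt(sd(corr - eeg), 0.5 * sd(eeg))
})

test_that("ROI amplitudes outside the artifact support are untouched", {
  m <- standardMontage()
  tl <- constantTimeline(60, rrMs = 1000, t0 = 2)
  cfaTpl <- defaultCfaTemplate(m, 15)          # support [-50, 450) ms
  vepTpl <- erpTemplate("vep", "distractor_move", c(200, 300), 5,
                        spatialWeights(m, "Cz", 4))
  r <- rPeakTimes(tl)
  evArt <- eventTable(r)
  evVep <- eventTable(r[10:40] + 0.6, type = "distractor_move")
  dur <- max(r) + 3
  # estimate the artifact on an artifact-only stretch (before any
  # distractor encounter), then correct the combined trace
  art <- renderEeg(evArt, list(CFA = cfaTpl), m, 250, dur)
  combined <- art + renderEeg(evVep, list(vep = vepTpl), m, 250, dur)
  est <- estimateCfa(art, 250, tl, nTriggers = 300, seed = 7,
                     periodS = c(2, max(r) - 2))
  corr <- subtractCfa(combined, est, tl)
  roi <- c("C1", "Cz", "C2")
  epB <- extractEpochs(combined, 250, evVep$time_s, c(-100, 400))
  epA <- extractEpochs(corr, 250, evVep$time_s, c(-100, 400))
  # VEP window 200-300 ms post movement = 800-900 ms post R: outside the
  # artifact support, so correction must not move the VEP ROI mean
  a <- mean(roiMeanAmplitude(epA, roi, c(200, 300)))
  b <- mean(roiMeanAmplitude(epB, roi, c(200, 300)))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("channel mismatch is an error", {
  tl <- constantTimeline(20, t0 = 2)
  eeg <- matrix(0, 4, 22 * 250, dimnames = list(letters[1:4], NULL))
  est <- estimateCfa(eeg, 250, tl, nTriggers = 50, seed = 1)
  bad <- eeg[1:3, ]
  expect_error(subtractCfa(bad, est, tl), "channel mismatch")
})
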