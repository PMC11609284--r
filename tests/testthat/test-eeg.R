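# EEG preprocessing, epoching, rejection and ROI amplitudes.

test_that("average reference zeroes the channel mean at every sample", {
  set.seed(1)
  eeg <- matrix(rnorm(8 * 2000), 8, 2000)
  out <- preprocessEeg(eeg, fs = 250)
  expect_lt(max(abs(colMeans(out))), 1e-9)
})

test_that("a common signal on all channels is annihilated", {
  t <- seq(0, 8, by = 1 / 250)
  common <- matrix(rep(sin(2 * pi * 7 * t), 5), 5, byrow = TRUE)
  out <- preprocessEeg(common, fs = 250, hpHz = 0)
  expect_lt(max(abs(out)), 1e-9)
})

test_that("the low-pass attenuates 50 Hz by at least 20 dB", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  x <- rbind(sin(2 * pi * 50 * t), -sin(2 * pi * 50 * t))
  y <- preprocessEeg(x, fs, hpHz = 0)   # opposite signs survive the reference
  expect_lt(20 * log10(interiorAmplitude(y[1, ])), -20)
  xp <- rbind(sin(2 * pi * 10 * t), -sin(2 * pi * 10 * t))
  yp <- preprocessEeg(xp, fs, hpHz = 0)
  expect_lt(abs(20 * log10(interiorAmplitude(yp[1, ]))), 1)
})

test_that("epochs are half-open windows with the exact sample count", {
  eeg <- matrix(rnorm(3 * 1000), 3, 1000,
                dimnames = list(c("a", "b", "c"), NULL))
  ep <- extractEpochs(eeg, 250, c(1, 2, 3), windowMs = c(-100, 1000))
  expect_equal(dim(epochData(ep)), c(3, 3, round(1100 * 250 / 1000)))
  expect_equal(epochTimesMs(ep)[1], -100)
  expect_lt(max(epochTimesMs(ep)), 1000)
})

test_that("a constant channel is identically zero after baseline", {
  eeg <- matrix(5, 2, 500, dimnames = list(c("a", "b"), NULL))
  ep <- extractEpochs(eeg, 250, c(0.8, 1.2), windowMs = c(-100, 400))
  expect_equal(max(abs(epochData(ep))), 0)
})

test_that("baseline-corrected epochs have zero baseline mean", {
  set.seed(3)
  eeg <- matrix(rnorm(4 * 2000, 10), 4, 2000)
  ep <- extractEpochs(eeg, 250, c(1, 2, 4), windowMs = c(-100, 600))
  rel <- epochTimesMs(ep)
  bl <- rel >= -100 & rel < 0
  base <- apply(epochData(ep)[, , bl, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-9)
})

test_that("events whose window leaves the signal are dropped and counted", {
  eeg <- matrix(rnorm(2 * 500), 2, 500)
  expect_message(
    ep <- extractEpochs(eeg, 250, c(0, 1, 100), windowMs = c(-100, 400)),
    NA)
  expect_equal(length(ep), 1L)
  expect_equal(ep@nDropped, 2L)
})

test_that("a rendered template is recovered exactly from its epoch", {
  m <- standardMontage()
  tpl <- erpTemplate("probe", "go_cue", c(200, 300), 4,
                     spatialWeights(m, "Cz", 4))
  ev <- eventTable(2.0, type = "go_cue")
  eeg <- renderEeg(ev, list(probe = tpl), m, fs = 250, durationS = 4)
  ep <- extractEpochs(eeg, 250, ev$time_s, c(-100, 500))
  rel <- epochTimesMs(ep)
  expected <- outer(tpl@channelWeights[m$label], templateWaveform(tpl, rel))
  expect_equal(epochData(ep)[1, , ], unname(expected), tolerance = 1e-12)
})

test_that("rejection removes exactly the epochs crossing 100 uV", {
  set.seed(4)
  dat <- array(rnorm(100 * 4 * 50, 0, 5), c(100, 4, 50))
  dat[7, 2, 10] <- 101
  dat[55, 4, 49] <- -130
  ep <- new("EpochSet", data = dat, windowMs = c(0, 200),
            baselineMs = numeric(0), eventType = "x", fs = 250,
            channels = paste0("ch", 1:4),
            info = data.frame(i = 1:100), nDropped = 0L)
  rej <- rejectEpochs(ep, 100)
  expect_equal(rej$exclusionRate, 0.02)
  expect_equal(length(rej$epochs), 98L)
  # just-below threshold survives
  dat2 <- dat[1:10, , , drop = FALSE]
  dat2[dat2 > 99] <- 99
  ep2 <- new("EpochSet", data = dat2, windowMs = c(0, 200),
             baselineMs = numeric(0), eventType = "x", fs = 250,
             channels = paste0("ch", 1:4),
             info = data.frame(i = 1:10), nDropped = 0L)
  expect_equal(rejectEpochs(ep2, 100)$exclusionRate, 0)
})

test_that("ROI means average the window and channels exactly", {
  dat <- array(1, c(2, 3, 100))          # constant 1 uV
  ep <- new("EpochSet", data = dat, windowMs = c(0, 400),
            baselineMs = numeric(0), eventType = "x", fs = 250,
            channels = c("a", "b", "c"),
            info = data.frame(i = 1:2), nDropped = 0L)
  expect_equal(unname(roiMeanAmplitude(ep, c("a", "b"), c(100, 300))),
               c(1, 1), ignore_attr = TRUE)
  # 3 uV square pulse covering exactly half of the window
  dat2 <- array(0, c(1, 1, 100))
  dat2[1, 1, 26:50] <- 3                 # samples at 100-196 ms
  ep2 <- new("EpochSet", data = dat2, windowMs = c(0, 400),
             baselineMs = numeric(0), eventType = "x", fs = 250,
             channels = "a", info = data.frame(i = 1), nDropped = 0L)
  expect_equal(unname(roiMeanAmplitude(ep2, "a", c(100, 300))), 1.5,
               ignore_attr = TRUE)
  # disjoint ROIs do not leak
  dat3 <- array(rep(c(2, 7, 0), each = 1), c(1, 3, 100))
  dat3[1, 1, ] <- 2; dat3[1, 2, ] <- 7; dat3[1, 3, ] <- 0
  ep3 <- new("EpochSet", data = dat3, windowMs = c(0, 400),
             baselineMs = numeric(0), eventType = "x", fs = 250,
             channels = c("a", "b", "c"),
             info = data.frame(i = 1), nDropped = 0L)
  expect_equal(unname(roiMeanAmplitude(ep3, "a", c(0, 400))), 2,
               ignore_attr = TRUE)
  expect_equal(unname(roiMeanAmplitude(ep3, "b", c(0, 400))), 7,
               ignore_attr = TRUE)
  expect_error(roiMeanAmplitude(ep3, "nope", c(0, 400)), "unknown channel")
})

test_that("hep/vep selection keeps only the first three pre-cue events", {
  cfg <- tinyConfig(conditions = c("systole", "diastole"))
  ses <- simulateSession(cfg, seed = 10, withEeg = FALSE)
  hep <- selectAnalysisEvents(ses, "hep")
  counts <- table(hep$trial_id)
  expect_true(all(counts <= 3))
  tr <- sessionTrials(ses)
  cue <- tr$go_cue_time_s[match(hep$trial_id, tr$trial_id)]
  expect_true(all(hep$time_s < cue))
  vep <- selectAnalysisEvents(ses, "vep")
  expect_true(all(table(vep$trial_id) <= 3))
  fb <- selectAnalysisEvents(ses, "feedback", detail = "commission")
  expect_true(all(fb$detail == "commission"))
})
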