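# Full-session simulation and the EEG forward model.

test_that("session composition follows the block design", {
  cfg <- tinyConfig(trialsPerBlock = 10L, goPerBlock = 7L, stopPerBlock = 3L)
  ses <- simulateSession(cfg, seed = 1, withEeg = FALSE)
  tr <- sessionTrials(ses)
  expect_equal(nrow(tr), 30L)
  tab <- table(tr$block, tr$trial_type)
  expect_true(all(tab[, "go"] == 7 & tab[, "stop"] == 3))
  expect_setequal(unique(tr$condition), c("systole", "diastole", "none"))
  # one feedback event per trial
  ev <- sessionEvents(ses)
  fb <- ev[ev$event_type == "feedback", ]
  expect_equal(sort(fb$trial_id), tr$trial_id)
})

test_that("go-cues respect the window and heartbeat constraints", {
  ses <- simulateSession(tinyConfig(), seed = 2, withEeg = FALSE)
  tr <- sessionTrials(ses)
  off <- tr$go_cue_time_s - tr$trial_start_s
  expect_true(all((off >= 2.9 & off <= 4.5) | tr$extended))
  expect_true(all(tr$n_precue_beats >= 3))
  expect_true(all(tr$trial_length_s >= 5.4 - 1e-9 | tr$extended))
  expect_true(all(tr$trial_length_s <= 7.0 + 1e-9 | tr$extended))
})

test_that("the control block has no distractor events", {
  ses <- simulateSession(tinyConfig(), seed = 3, withEeg = FALSE)
  ev <- sessionEvents(ses)
  noneTrials <- sessionTrials(ses)$trial_id[
    sessionTrials(ses)$condition == "none"]
  mv <- ev[ev$event_type == "distractor_move", ]
  expect_false(any(mv$trial_id %in% noneTrials))
  expect_gt(nrow(mv), 0)
})

test_that("the same seed reproduces the session bit-exactly", {
  cfg <- tinyConfig()
  a <- simulateSession(cfg, seed = 4)
  b <- simulateSession(cfg, seed = 4)
  expect_identical(sessionEvents(a), sessionEvents(b))
  expect_identical(sessionTrials(a), sessionTrials(b))
  expect_identical(ecgSamples(sessionEcg(a)), ecgSamples(sessionEcg(b)))
  expect_identical(sessionEeg(a), sessionEeg(b))
})

test_that("event cardiac offsets lie inside the preceding RR interval", {
  ses <- simulateSession(tinyConfig(), seed = 5, withEeg = FALSE)
  ev <- sessionEvents(ses)
  tl <- sessionTimeline(ses)
  ok <- !is.na(ev$cardiac_offset_ms)
  expect_true(all(ev$cardiac_offset_ms[ok] >= 0))
  i <- findInterval(ev$time_s[ok], rPeakTimes(tl))
  rr <- c(rrIntervals(tl), Inf)[i]
  expect_true(all(ev$cardiac_offset_ms[ok] < rr))
})

test_that("rendering is linear: superposed templates sum exactly", {
  m <- standardMontage()
  tplA <- erpTemplate("a", "go_cue", c(100, 300), 4, spatialWeights(m, "Cz", 4))
  tplB <- erpTemplate("b", "go_cue", c(200, 400), -2, spatialWeights(m, "Fz", 3))
  ev <- eventTable(c(1.0, 2.5), type = "go_cue")
  both <- renderEeg(ev, list(a = tplA, b = tplB), m, 250, 4)
  sep <- renderEeg(ev, list(a = tplA), m, 250, 4) +
    renderEeg(ev, list(b = tplB), m, 250, 4)
  expect_equal(both, sep, tolerance = 1e-12)
  # no events, no noise: silence
  none <- renderEeg(eventTable(numeric(0)), list(a = tplA), m, 250, 2)
  expect_true(all(none == 0))
})

test_that("noise-free analysis recovers injected amplitudes exactly", {
  m <- standardMontage()
  cfg <- tinyConfig(noiseSd = 0, cfaAmplitude = 0, triggerJitterSdMs = 0,
                    templates = defaultErpTemplates(m)["HEP"])
  ses <- simulateSession(cfg, seed = 6)
  ev <- selectAnalysisEvents(ses, "hep")
  ep <- extractEpochs(sessionEeg(ses), 250, ev$time_s, c(-100, 1000),
                      info = ev)
  roi <- c("FC1", "FCz", "FC2", "C1", "Cz", "C2")
  amp <- roiMeanAmplitude(ep, roi, c(300, 400))
  tpl <- cfg@templates$HEP
  rel <- epochTimesMs(ep)
  sIdx <- rel >= 300 & rel < 400
  expected <- mean(outer(tpl@channelWeights[roi],
                         templateWaveform(tpl, rel[sIdx])))
  gain <- ifelse(epochInfo(ep)$condition == "diastole",
                 templateGain(tpl, "diastole"), 1)
  expect_equal(as.numeric(amp), unname(expected * gain), tolerance = 1e-9)
})

test_that("injected P2 condition difference shows in the ROI", {
  roi <- c("F1", "Fz", "F2", "FC1", "FCz", "FC2", "C1", "Cz", "C2")
  diffPositive <- vapply(1:25, function(s) {
    cfg <- tinyConfig(conditions = c("systole", "diastole"),
                      trialsPerBlock = 8L, goPerBlock = 6L,
                      stopPerBlock = 2L, eegFs = 125)
    ses <- suppressMessages(simulateSession(cfg, seed = 100 + s))
    ev <- selectAnalysisEvents(ses, "vep")
    ep <- extractEpochs(sessionEeg(ses), 125, ev$time_s, c(-100, 1000),
                        info = ev)
    amp <- roiMeanAmplitude(ep, roi, c(200, 300))
    mean(amp[epochInfo(ep)$condition == "diastole"]) >
      mean(amp[epochInfo(ep)$condition == "systole"])
  }, TRUE)
  expect_gte(mean(diffPositive), 0.95)
})

test_that("ground truth records per-condition template gains", {
  ses <- simulateSession(tinyConfig(), seed = 7, withEeg = FALSE)
  g <- groundTruth(ses)$gains
  expect_true(all(c("template", "condition", "gain") %in% names(g)))
  expect_equal(g$gain[g$template == "P2" & g$condition == "systole"], 0.7)
  expect_equal(g$gain[g$template == "HEP" & g$condition == "diastole"], 0.7)
})
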