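# Linear component decomposition, ECG-coherence ranking and removal.

test_that("reconstruction without removal is lossless", {
  set.seed(1)
  mixing <- matrix(rnorm(12), 4, 3)
  sources <- matrix(rnorm(3 * 500), 3, 500)
  cs <- componentSet(sources, mixing, fs = 250, channels = letters[1:4])
  expect_lt(max(abs(removeComponents(cs) - mixing %*% sources)), 1e-12)
})

test_that("removing one source leaves exactly the other's contribution", {
  set.seed(2)
  wA <- c(1, 0.5, 0); wB <- c(0, 1, -1)
  sA <- sin(2 * pi * (1:400) / 50)
  sB <- rnorm(400)
  cs <- componentSet(rbind(sA, sB), cbind(wA, wB), fs = 200,
                     channels = c("x", "y", "z"),
                     componentNames = c("A", "B"))
  out <- removeComponents(cs, indices = 2)
  expect_equal(out, outer(wA, sA), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("removing everything warns and returns silence", {
  cs <- componentSet(matrix(1, 1, 10), matrix(1, 2, 1), 100, c("a", "b"))
  expect_warning(out <- removeComponents(cs, 1), "zero signal")
  expect_true(all(out == 0))
  expect_error(removeComponents(cs, 5), "out of range")
})

test_that("the ECG itself gets coherence ~1 and rank 1", {
  tl <- simulateRRSeries(60, 30, 60, seed = 3)
  ecg <- synthesizeEcg(tl, 250)
  x <- ecgSamples(ecg)
  set.seed(4)
  sources <- rbind(x, rnorm(length(x)), rep(2, length(x)))
  cs <- componentSet(sources, matrix(rnorm(9), 3, 3), fs = 250,
                     channels = c("a", "b", "c"),
                     componentNames = c("ecgcopy", "noise", "flat"))
  cs <- rankComponentsByEcgCoherence(cs, x, ecgFs = 250)
  coh <- componentCoherence(cs)
  expect_gt(coh[["ecgcopy"]], 0.95)
  expect_lt(coh[["noise"]], 0.35)
  expect_true(is.na(coh[["flat"]]))                  # degenerate: undefined
  expect_equal(componentRank(cs)[1], 1L)             # ECG copy first
  expect_equal(componentRank(cs)[3], 3L)             # constant ranked last
})

test_that("the scalar correlation estimator agrees on the trivial case", {
  tl <- simulateRRSeries(60, 30, 40, seed = 5)
  x <- ecgSamples(synthesizeEcg(tl, 250))
  cs <- componentSet(rbind(x), matrix(1, 1, 1), 250, "a", "ecgcopy")
  cs <- rankComponentsByEcgCoherence(cs, x, ecgFs = 250,
                                     method = "correlation")
  expect_equal(unname(componentCoherence(cs)[1]), 1)
})

test_that("an R-locked source in a mixture is ranked first", {
  cfg <- tinyConfig(conditions = "none",
                    templates = defaultErpTemplates(standardMontage())["HEP"],
                    noiseSd = 5)
  ses <- simulateSession(cfg, seed = 6)
  cs <- sessionComponentSet(ses)
  expect_lt(max(abs(removeComponents(cs) - sessionEeg(ses))), 1e-9)
  cs <- rankComponentsByEcgCoherence(cs, sessionEcg(ses))
  first <- cs@componentNames[componentRank(cs)[1]]
  expect_true(first %in% c("HEP", "CFA"))   # cardiac-locked sources on top
  # top-30 truncation keeps the ranking prefix
  cs30 <- rankComponentsByEcgCoherence(cs, sessionEcg(ses), topN = 30)
  expect_length(componentRank(cs30), 30)
  expect_equal(componentRank(cs30), componentRank(cs)[1:30])
})

test_that("removing the HEP-carrying source empties the HEP ROI", {
  cfg <- tinyConfig(conditions = "none", noiseSd = 0, cfaAmplitude = 0,
                    templates = defaultErpTemplates(standardMontage())["HEP"])
  ses <- simulateSession(cfg, seed = 7)
  cs <- sessionComponentSet(ses)
  clean <- removeComponents(cs, which(cs@componentNames == "HEP"))
  ev <- selectAnalysisEvents(ses, "hep")
  ep <- extractEpochs(clean, 250, ev$time_s, c(-100, 1000))
  amp <- roiMeanAmplitude(ep, c("FC1", "FCz", "FC2", "C1", "Cz", "C2"),
                          c(300, 400))
  expect_lt(max(abs(amp)), 1e-9)
})

test_that("pca decomposition hook reconstructs losslessly", {
  set.seed(8)
  eeg <- matrix(rnorm(6 * 300), 6, 300, dimnames = list(letters[1:6], NULL))
  cs <- pcaComponentSet(eeg, fs = 100)
  expect_lt(max(abs(removeComponents(cs) - eeg)), 1e-9)
})
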