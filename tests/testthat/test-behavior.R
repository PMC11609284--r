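# Behavioural endpoints: accuracy, medians, integration-method SSRT.

test_that("integration SSRT reproduces the hand-ranked example", {
  # n=5, p=0.4 -> k = ceil(2) = 2 -> 420 - 180 = 240
  expect_equal(estimateSsrtIntegration(c(400, 420, 440, 460, 480), 0.4, 180),
               240)
})

test_that("p = 1 uses the maximum go RT", {
  rts <- c(512, 430, 488)
  expect_equal(estimateSsrtIntegration(rts, 1, 100), max(rts) - 100)
})

test_that("p = 0 is flagged as undefined", {
  expect_warning(out <- estimateSsrtIntegration(c(400, 450), 0, 100),
                 "undefined")
  expect_true(is.na(out))
})

test_that("SSRT is translation-equivariant", {
  rts <- c(380, 401, 455, 470, 530, 610)
  for (cc in c(-50, 25, 100)) {
    expect_equal(estimateSsrtIntegration(rts + cc, 0.45, 200 + cc),
                 estimateSsrtIntegration(rts, 0.45, 200))
  }
})

test_that("omissions are replaced by the maximum observed RT", {
  rts <- c(400, NA, 500, NA)
  # with max-RT correction: sorted 400,500,500,500; p=.75 -> k=3 -> 500
  expect_equal(estimateSsrtIntegration(rts, 0.75, 0), 500)
  # with drop: sorted 400,500; k = ceil(1.5) = 2 -> 500
  expect_equal(estimateSsrtIntegration(rts, 0.75, 0,
                                       omissionCorrection = "drop"), 500)
  # difference shows at lower p
  expect_equal(estimateSsrtIntegration(rts, 0.5, 0), 500)
  expect_equal(estimateSsrtIntegration(rts, 0.5, 0,
                                       omissionCorrection = "drop"), 400)
})

test_that("medians follow the mean-of-middle-two convention", {
  expect_equal(medianMs(c(100, 200, 300)), 200)
  expect_equal(medianMs(c(100, 200)), 150)
  expect_warning(out <- medianMs(numeric(0)), "median undefined")
  expect_true(is.na(out))
})

test_that("accuracy summaries count omissions and commissions", {
  trials <- data.frame(
    trial_id = 1:60, condition = "systole",
    trial_type = rep(c("go", "stop"), c(10, 50)),
    responded = c(rep(c(TRUE, FALSE), c(9, 1)),
                  rep(c(TRUE, FALSE), c(25, 25))),
    rt_ms = c(rnorm(9, 450, 30), NA, rnorm(25, 430, 30), rep(NA, 25)),
    ssd_ms = c(rep(NA, 10), rep(c(200, 250), 25)))
  su <- summarizeBehavior(trials)
  expect_equal(su$go_omission_pct, 10)
  expect_equal(su$go_hit_pct, 90)
  expect_equal(su$stop_commission_pct, 50)
  expect_equal(su$p_respond_stop, 0.5)
  expect_equal(su$median_ssd_ms, 225)
})

test_that("an all-correct session has zero omission and commission", {
  trials <- data.frame(
    trial_id = 1:20, condition = "none",
    trial_type = rep(c("go", "stop"), each = 10),
    responded = rep(c(TRUE, FALSE), each = 10),
    rt_ms = c(rnorm(10, 450, 20), rep(NA, 10)),
    ssd_ms = c(rep(NA, 10), rep(300, 10)))
  expect_warning(su <- summarizeBehavior(trials), NA)
  expect_equal(su$go_omission_pct, 0)
  expect_equal(su$stop_commission_pct, 0)
  expect_true(is.na(su$ssrt_ms))  # p(respond|stop) = 0: flagged missing
})

test_that("median SSD agrees with a brute recount of the trial log", {
  loop <- runStaircaseLoop(raceModelParams(), nStop = 300, seed = 9)
  trials <- data.frame(trial_id = seq_along(loop$ssdTrace),
                       condition = "systole", trial_type = "stop",
                       responded = loop$responded, rt_ms = NA_real_,
                       ssd_ms = loop$ssdTrace)
  go <- data.frame(trial_id = 1000 + 1:50, condition = "systole",
                   trial_type = "go", responded = TRUE,
                   rt_ms = rnorm(50, 450, 40), ssd_ms = NA_real_)
  su <- summarizeBehavior(rbind(trials, go))
  # independent recount: sort and average the middle values by hand
  s <- sort(loop$ssdTrace)
  n <- length(s)
  recount <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  expect_identical(su$median_ssd_ms, recount)
})

test_that("the estimator recovers a known SSRT from staircase sessions", {
  set.seed(21)
  err <- replicate(30, {
    pr <- raceModelParams(ssrtTrue = 220)
    loop <- runStaircaseLoop(pr, nStop = 500)
    rts <- vapply(1:1000, function(i)
      sampleRaceOutcome(pr, trialType = "go")$rtMs, 0)
    estimateSsrtIntegration(rts, loop$pRespond, mean(loop$ssdTrace)) - 220
  })
  expect_lt(abs(mean(err)), 15)
  expect_lt(sqrt(mean(err^2)), 25)
})
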