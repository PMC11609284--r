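# Independent-race agent: ex-Gaussian go process racing a constant-latency
# stop process. A response occurs on a stop trial iff the go process
# finishes before SSD + SSRT.

#' Construct race-model agent parameters
#'
#' @param goMu,goSigma,goTau ex-Gaussian go finishing time parameters (ms).
#' @param ssrtTrue true stop finishing time (ms).
#' @param omissionRate probability of a go omission independent of timing.
#' @return a [RaceModelParams-class]
#' @export
raceModelParams <- function(goMu = 400, goSigma = 40, goTau = 60,
                            ssrtTrue = 220, omissionRate = 0) {
  new("RaceModelParams", goMu = goMu, goSigma = goSigma, goTau = goTau,
      ssrtTrue = ssrtTrue, omissionRate = omissionRate)
}

# one ex-Gaussian draw (ms), truncated at zero from below by resampling
rExGauss <- function(n, mu, sigma, tau) {
  x <- rnorm(n, mu, sigma) + rexp(n, 1 / tau)
  while (any(bad <- x <= 0))
    x[bad] <- rnorm(sum(bad), mu, sigma) + rexp(sum(bad), 1 / tau)
  x
}

#' Sample one trial outcome from the race model
#'
#' On a go trial the agent responds unless a random omission occurs or the
#' go finishing time exceeds the response window (censored responses are
#' coded as omissions). On a stop trial the agent responds iff the go
#' finishing time beats SSD + SSRT; the reaction time is reported only when
#' a response occurred.
#'
#' @param params a [RaceModelParams-class].
#' @param ssdMs stop-signal delay in ms (stop trials; must be >= 0).
#' @param trialType "go" or "stop".
#' @param goDisplayMs response window on go trials (ms).
#' @param seed optional integer seed.
#' @return list(responded = logical, rtMs = numeric or NA)
#' @export
sampleRaceOutcome <- function(params, ssdMs = NA, trialType = c("go", "stop"),
                              goDisplayMs = 1500, seed = NULL) {
  trialType <- match.arg(trialType)
  if (!is.null(seed)) set.seed(seed)
  goFt <- rExGauss(1, params@goMu, params@goSigma, params@goTau)
  if (trialType == "go") {
    omitted <- runif(1) < params@omissionRate || goFt > goDisplayMs
    if (omitted) return(list(responded = FALSE, rtMs = NA_real_))
    return(list(responded = TRUE, rtMs = goFt))
  }
  if (is.na(ssdMs) || ssdMs < 0) stop("stop trials need ssdMs >= 0")
  if (goFt < ssdMs + params@ssrtTrue)
    list(responded = TRUE, rtMs = goFt)
  else
    list(responded = FALSE, rtMs = NA_real_)
}

#' Run the adaptive staircase closed loop against the race-model agent
#'
#' Simulates \code{nStop} consecutive stop trials in one condition, updating
#' the stop-signal-delay staircase after every trial. This is the
#' closed-loop check that the tracking procedure holds stopping performance
#' at 50\%.
#'
#' @param params a [RaceModelParams-class].
#' @param staircase a [StaircaseState-class]; default the study staircase.
#' @param nStop number of stop trials.
#' @param seed optional integer seed.
#' @return list with \code{pRespond} (proportion of stop trials with a
#'   response), \code{ssdTrace} (SSD before each trial, ms),
#'   \code{responded} (logical per trial) and the final staircase state.
#' @export
runStaircaseLoop <- function(params, staircase = staircaseState(),
                             nStop = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ssdTrace <- numeric(nStop)
  responded <- logical(nStop)
  for (i in seq_len(nStop)) {
    ssdTrace[i] <- staircase@ssdMs
    out <- sampleRaceOutcome(params, ssdMs = staircase@ssdMs,
                             trialType = "stop")
    responded[i] <- out$responded
    staircase <- updateStaircase(staircase, respondedOnStop = out$responded)
  }
  list(pRespond = mean(responded), ssdTrace = ssdTrace,
       responded = responded, staircase = staircase)
}
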