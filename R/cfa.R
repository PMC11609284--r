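# Cardiac-field-artifact estimation and subtraction.
#
# Random triggers are scattered uniformly over the cardiac cycles of the
# period of interest and classified as systole or diastole by their position
# in the cycle. Per phase, the trigger-locked (-1000, 2000) ms average
# (baseline-corrected 100 ms pre-trigger) estimates the artifact as the
# original procedure specifies. Because random trigger offsets smear an
# R-locked artifact, the estimator additionally re-epochs the same
# classified triggers time-locked to each trigger's preceding R-peak; these
# R-locked templates are what [subtractCfa()] removes from the data trace.

#' Estimate the cardiac field artifact from random triggers
#'
#' @param eeg channels x samples matrix (channel rownames).
#' @param fs sampling rate (Hz).
#' @param timeline the [CardiacTimeline-class] of the recording.
#' @param nTriggers number of random triggers.
#' @param seed optional integer seed.
#' @param windowMs trigger-locked template window (ms).
#' @param rWindowMs R-locked template window (ms).
#' @param periodS optional length-2 restriction of trigger placement (s),
#'   e.g. the distractor-encounter period.
#' @return a [CfaEstimate-class]; phases with fewer than 10 triggers warn
#' @export
estimateCfa <- function(eeg, fs, timeline, nTriggers = 400, seed = NULL,
                        windowMs = c(-1000, 2000), rWindowMs = c(-200, 1500),
                        periodS = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- rPeakTimes(timeline)
  durS <- ncol(eeg) / fs
  lo <- max(r[1], -windowMs[1] / 1000, if (!is.null(periodS)) periodS[1] else -Inf)
  hi <- min(r[length(r)], durS - windowMs[2] / 1000,
            if (!is.null(periodS)) periodS[2] else Inf)
  if (hi <= lo) stop("recording too short for the CFA template window")
  trig <- sort(runif(nTriggers, lo, hi))
  phase <- codeCardiacPhase(trig, timeline)
  labels <- rownames(eeg)

  avgFor <- function(times, win, baseline) {
    ep <- extractEpochs(eeg, fs, times, windowMs = win,
                        baselineMs = baseline, eventType = "cfa_trigger")
    if (!length(ep)) return(NULL)
    m <- colMeans(ep@data, dims = 1)
    rownames(m) <- labels
    m
  }

  triggerLocked <- list()
  rLocked <- list()
  nUsed <- integer(0)
  for (ph in c("systole", "diastole")) {
    tPh <- trig[!is.na(phase) & phase == ph]
    nUsed[ph] <- length(tPh)
    if (length(tPh) < 10)
      warning("only ", length(tPh), " ", ph, " triggers")
    if (!length(tPh)) next
    triggerLocked[[ph]] <- avgFor(tPh, windowMs, c(-100, 0))
    rPrev <- r[findInterval(tPh, r)]
    rLocked[[ph]] <- avgFor(rPrev, rWindowMs, NULL)
  }
  new("CfaEstimate", triggerLocked = triggerLocked, rLocked = rLocked,
      windowMs = as.numeric(windowMs), rWindowMs = as.numeric(rWindowMs),
      fs = fs, channels = labels, nTriggers = nUsed)
}

#' Subtract the estimated cardiac field artifact from a data trace
#'
#' Subtracts the R-locked artifact template at every R-peak of the
#' recording, identically for all experimental conditions. The subtraction
#' support of each beat is clipped to its RR interval so every sample is
#' corrected exactly once.
#'
#' @param eeg channels x samples matrix.
#' @param cfa a [CfaEstimate-class].
#' @param timeline the recording's [CardiacTimeline-class].
#' @param phase which phase template to subtract: "both" (average of the
#'   systole- and diastole-derived templates), "systole" or "diastole".
#' @return corrected channels x samples matrix
#' @export
subtractCfa <- function(eeg, cfa, timeline,
                        phase = c("both", "systole", "diastole")) {
  phase <- match.arg(phase)
  if (!identical(rownames(eeg), cfa@channels))
    stop("channel mismatch between data and CFA estimate")
  tpl <- switch(phase,
    both = {
      avail <- cfa@rLocked[!vapply(cfa@rLocked, is.null, TRUE)]
      if (!length(avail)) stop("CFA estimate has no R-locked template")
      Reduce(`+`, avail) / length(avail)
    },
    systole = cfa@rLocked[["systole"]],
    diastole = cfa@rLocked[["diastole"]])
  if (is.null(tpl)) stop("requested phase template unavailable")
  fs <- cfa@fs
  relS0 <- round(cfa@rWindowMs[1] * fs / 1000)     # template sample offset
  r <- rPeakTimes(timeline)
  rr <- rrIntervals(timeline)
  rrForBeat <- c(rr, if (length(rr)) mean(rr) else 1000)
  nS <- ncol(eeg)
  out <- eeg
  for (i in seq_along(r)) {
    rSamp <- round(r[i] * fs)                      # 0-based
    nBeat <- round(rrForBeat[i] * fs / 1000)
    tIdx <- which(relS0 + seq_len(ncol(tpl)) - 1L >= 0)[seq_len(nBeat)]
    tIdx <- tIdx[!is.na(tIdx) & tIdx <= ncol(tpl)]
    if (!length(tIdx)) next
    dIdx <- rSamp + (relS0 + tIdx - 1L) + 1L       # back to 1-based signal
    ok <- dIdx >= 1L & dIdx <= nS
    out[, dIdx[ok]] <- out[, dIdx[ok]] - tpl[, tIdx[ok]]
  }
  out
}

#' R-locked mean-square power of a recording
#'
#' Mean square of the R-locked average waveform (no baseline correction)
#' over the given post-R window; the quantity the CFA correction is meant
#' to suppress.
#'
#' @param eeg channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param timeline a [CardiacTimeline-class].
#' @param windowMs window around the R-peak (ms).
#' @return numeric mean-square power (microvolts squared)
#' @export
rLockedMeanSquare <- function(eeg, fs, timeline, windowMs = c(0, 700)) {
  ep <- extractEpochs(eeg, fs, rPeakTimes(timeline), windowMs = windowMs,
                      baselineMs = NULL, eventType = "r_peak")
  if (!length(ep)) stop("no usable R-locked epochs")
  avg <- colMeans(ep@data, dims = 1)
  mean(avg^2)
}
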