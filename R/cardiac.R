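# Synthetic cardiac timeline and ECG trace.
#
# RR generation uses a lag-1 autocorrelated Gaussian process whose variance
# is calibrated so that the expected RMSSD matches the request: for an AR(1)
# with stationary variance v and coefficient phi,
# E[(RR[i+1] - RR[i])^2] = 2 v (1 - phi), so v = rmssd^2 / (2 (1 - phi)).

#' Construct a CardiacTimeline from RR intervals
#'
#' @param rrMs numeric vector of RR intervals in ms.
#' @param t0 time of the first R-peak in seconds.
#' @return a [CardiacTimeline-class]
#' @export
cardiacTimeline <- function(rrMs, t0 = 0) {
  stopifnot(all(rrMs > 0))
  r <- t0 + cumsum(c(0, rrMs)) / 1000
  new("CardiacTimeline", rPeakTimes = r, rrIntervals = as.numeric(rrMs),
      tEndOffsets = tEndOffsetFor(c(rrMs, mean(rrMs))))
}

# End-of-T estimate per beat: T-center (250 ms) + 2 T-widths (2 x 50 ms) at
# RR = 1000 ms, scaled by sqrt(RR / 1000) so the estimate tracks heart rate;
# clamped below the RR interval so systole never swallows the whole cycle.
tEndOffsetFor <- function(rrMs) {
  pmin(350 * sqrt(rrMs / 1000), 0.9 * rrMs)
}

#' Simulate an RR-interval series with controlled heart rate and RMSSD
#'
#' Draws a lag-1 autocorrelated Gaussian RR process around 60000 / meanHrBpm
#' ms with variance calibrated so the expected root mean square of
#' successive differences equals \code{rmssdMs}. Non-positive draws are
#' resampled (they are vanishingly rare for physiological parameter
#' combinations); a variability request incompatible with the heart rate is
#' a parameter error.
#'
#' @param meanHrBpm mean heart rate in bpm, in (30, 180).
#' @param rmssdMs requested RMSSD in ms (>= 0).
#' @param nBeats number of beats (>= 2).
#' @param seed optional integer seed.
#' @param phi lag-1 autocorrelation of the RR process.
#' @param t0 time of the first R-peak (s).
#' @return a [CardiacTimeline-class] with \code{nBeats} R-peaks.
#' @examples
#' tl <- simulateRRSeries(58.2, 53.5, 300, seed = 1)
#' computeHrHrv(rrIntervals(tl))
#' @export
simulateRRSeries <- function(meanHrBpm, rmssdMs, nBeats, seed = NULL,
                             phi = 0.3, t0 = 0) {
  if (meanHrBpm <= 30 || meanHrBpm >= 180)
    stop("meanHrBpm must be in (30, 180)")
  if (nBeats < 2) stop("nBeats must be >= 2")
  if (rmssdMs < 0) stop("rmssdMs must be >= 0")
  if (abs(phi) >= 1) stop("phi must be in (-1, 1)")
  if (!is.null(seed)) set.seed(seed)
  mu <- 60000 / meanHrBpm
  v <- rmssdMs^2 / (2 * (1 - phi))
  if (sqrt(v) > mu / 3)
    stop("requested RMSSD too large for this heart rate")
  nInt <- nBeats - 1L
  if (v == 0) return(cardiacTimeline(rep(mu, nInt), t0 = t0))
  sdInnov <- sqrt(v * (1 - phi^2))
  x <- numeric(nInt)
  draw <- function(m, s) {
    for (k in 1:100) {
      z <- rnorm(1, m, s)
      if (z > -mu + 1e-9) return(z)   # keep RR = mu + z positive
    }
    stop("could not draw a positive RR interval")
  }
  x[1] <- draw(0, sqrt(v))
  for (i in seq_len(nInt - 1L))
    x[i + 1L] <- draw(phi * x[i], sdInnov)
  cardiacTimeline(mu + x, t0 = t0)
}

# ECG beat template: piecewise Gaussian bumps (Q, R, S, T) in microvolts as
# a function of time since the R-peak (s). T-wave center and width scale
# with sqrt(RR / 1000) so that T-end = T-center + 2 T-widths matches the
# timeline's per-beat t_end estimate.
ecgBeatWaveform <- function(tSec, rrSec = 1) {
  s <- sqrt(rrSec)
  g <- function(c, a, w) a * exp(-0.5 * ((tSec - c) / w)^2)
  g(-0.030, -120, 0.008) + g(0, 1000, 0.009) + g(0.030, -180, 0.009) +
    g(0.250 * s, 250, 0.050 * s)
}

#' Synthesize an ECG trace from a cardiac timeline
#'
#' Renders one QRST complex per R-peak (piecewise Gaussian Q, R, S and T
#' bumps; T timing scales with sqrt(RR)) on a uniform sample grid. The
#' global maximum of every beat falls within one sample of the nominal
#' R-peak time, and the T bump provides positive area in the 240-340 ms
#' post-R window used for T-wave quantification. Beats shorter than the
#' template support are truncated at the next beat with a warning.
#'
#' @param timeline a [CardiacTimeline-class].
#' @param fs sampling rate in Hz (>= 250).
#' @param padS zero padding before the first and after the last R-peak (s).
#' @return an [EcgSignal-class]
#' @export
synthesizeEcg <- function(timeline, fs = 500, padS = 1) {
  if (fs < 250) stop("fs must be >= 250 Hz")
  r <- rPeakTimes(timeline)
  rr <- rrIntervals(timeline)
  t0 <- r[1] - padS
  nS <- ceiling((r[length(r)] + padS - t0) * fs) + 1L
  x <- numeric(nS)
  tGrid <- t0 + (seq_len(nS) - 1) / fs
  rrForBeat <- c(rr, if (length(rr)) mean(rr) else 1000) / 1000
  truncated <- FALSE
  for (i in seq_along(r)) {
    rrSec <- rrForBeat[i]
    # support: from just before the Q to the end of the T (or the next beat)
    hi <- 0.250 * sqrt(rrSec) + 5 * 0.050 * sqrt(rrSec)
    if (i < length(r) && hi > rrSec - 0.02) {
      hi <- rrSec - 0.02
      truncated <- TRUE
    }
    i0 <- max(1L, ceiling((r[i] - 0.08 - t0) * fs) + 1L)
    i1 <- min(nS, floor((r[i] + hi - t0) * fs) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    x[idx] <- x[idx] + ecgBeatWaveform(tGrid[idx] - r[i], rrSec)
  }
  if (truncated)
    warning("some RR intervals are shorter than the beat template; T waves truncated")
  new("EcgSignal", samples = x, fs = fs,
      trueRIndices = as.integer(round((r - t0) * fs) + 1L))
}
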