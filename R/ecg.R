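# Offline ECG analysis: 1-40 Hz zero-phase FIR filtering, adaptive R-peak
# detection, HR/RMSSD, R-amplitude and T-wave area, and post-hoc cardiac
# phase coding (systole: R-peak to end of T; diastole: end of T to next R).

#' Band-pass filter an ECG trace (1-40 Hz, zero-phase FIR, Hamming window)
#'
#' Designs a linear-phase FIR band-pass with a Hamming window and applies it
#' forwards and backwards (zero net phase). The filter order scales with the
#' sampling rate so the transition band stays about 1 Hz wide.
#'
#' @param x numeric samples, or an [EcgSignal-class].
#' @param fs sampling rate in Hz (> 80); taken from the object when an
#'   EcgSignal is given.
#' @param bandHz passband edges in Hz.
#' @return filtered samples (same class as the input)
#' @export
bandpassEcg <- function(x, fs = NULL, bandHz = c(1, 40)) {
  obj <- NULL
  if (is(x, "EcgSignal")) {
    obj <- x
    fs <- x@fs
    x <- x@samples
  }
  if (is.null(fs) || fs <= 80) stop("fs must be > 80 Hz")
  ord <- 2L * round(1.65 * fs)          # ~1 Hz Hamming transition width
  b <- signal::fir1(ord, bandHz / (fs / 2), type = "pass",
                    window = signal::hamming(ord + 1))
  y <- .firFiltfilt(b, x)
  if (!is.null(obj)) return(initialize(obj, samples = as.numeric(y)))
  as.numeric(y)
}

# zero-phase FIR application: FFT convolution forwards, then backwards, so
# the linear-phase delays cancel; the result has squared magnitude response
# and no phase distortion
.firFiltfilt <- function(b, x) {
  n <- length(x)
  L <- length(b)
  y <- signal::fftfilt(b, c(x, numeric(L)))
  y <- rev(signal::fftfilt(b, rev(y)))
  as.numeric(y[seq_len(n)])
}

# frequency response magnitude of the same design at given frequencies
# (single pass); used to audit pass/stop-band behaviour
firBandpassResponse <- function(fs, fHz, bandHz = c(1, 40)) {
  ord <- 2L * round(1.65 * fs)
  b <- signal::fir1(ord, bandHz / (fs / 2), type = "pass",
                    window = signal::hamming(ord + 1))
  k <- seq_along(b) - 1
  vapply(fHz, function(f)
    Mod(sum(b * exp(-2i * pi * f * k / fs))), 0)
}

#' Detect R-peaks with an adaptive threshold and refractory period
#'
#' Local maxima exceeding half of the largest positive deflection, with a
#' refractory period during which only the larger of two competing peaks
#' survives. The relative threshold makes detection invariant to amplitude
#' scaling; a flat (or non-positive) trace yields no detections.
#'
#' @param x numeric samples (ideally band-passed), or an
#'   [EcgSignal-class].
#' @param fs sampling rate (Hz); from the object when given.
#' @param refractoryS minimum R-R separation (s).
#' @param rel threshold as a fraction of the global maximum.
#' @return numeric vector of R-peak times (s, relative to the first sample)
#' @export
detectRPeaks <- function(x, fs = NULL, refractoryS = 0.25, rel = 0.5) {
  if (is(x, "EcgSignal")) {
    fs <- x@fs
    x <- x@samples
  }
  if (is.null(fs)) stop("fs required")
  mx <- max(x)
  if (!is.finite(mx) || mx <= 0 || mx == min(x)) return(numeric(0))
  thr <- rel * mx
  n <- length(x)
  isMax <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
             FALSE)
  cand <- which(isMax & x > thr)
  if (!length(cand)) return(numeric(0))
  # greedy by amplitude: accept unless within the refractory period of an
  # already accepted (larger) peak
  cand <- cand[order(x[cand], decreasing = TRUE)]
  accepted <- integer(0)
  refSamp <- refractoryS * fs
  for (i in cand) {
    if (!length(accepted) || min(abs(accepted - i)) > refSamp)
      accepted <- c(accepted, i)
  }
  (sort(accepted) - 1) / fs
}

#' Mean heart rate and RMSSD from RR intervals
#'
#' @param rrMs RR intervals in ms.
#' @return named numeric: meanHrBpm (60000 / mean RR) and rmssdMs (root
#'   mean square of successive differences; NA with a warning when fewer
#'   than two intervals are available)
#' @examples
#' computeHrHrv(c(800, 1000))  # 66.7 bpm, RMSSD 200
#' @export
computeHrHrv <- function(rrMs) {
  if (!length(rrMs)) stop("need at least one RR interval")
  hr <- 60000 / mean(rrMs)
  if (length(rrMs) < 2) {
    warning("fewer than 2 RR intervals; RMSSD undefined")
    return(c(meanHrBpm = hr, rmssdMs = NA_real_))
  }
  c(meanHrBpm = hr, rmssdMs = sqrt(mean(diff(rrMs)^2)))
}

#' Code the cardiac phase of event times
#'
#' Systole runs from the R-peak (inclusive) to the beat's end-of-T estimate;
#' diastole from just after T-end to the end of the RR interval. Events
#' before the first R-peak are coded NA with a warning.
#'
#' @param eventTimesS event times (s).
#' @param timeline a [CardiacTimeline-class].
#' @return character vector in \{"systole", "diastole", NA\}
#' @export
codeCardiacPhase <- function(eventTimesS, timeline) {
  r <- rPeakTimes(timeline)
  te <- tEndOffsets(timeline)
  i <- findInterval(eventTimesS, r)
  phase <- rep(NA_character_, length(eventTimesS))
  ok <- i >= 1
  if (any(!ok)) warning(sum(!ok), " events precede the first R-peak")
  off <- (eventTimesS[ok] - r[i[ok]]) * 1000
  phase[ok] <- ifelse(off <= te[i[ok]], "systole", "diastole")
  phase
}

#' R-peak amplitude and T-wave area per condition
#'
#' For each detected beat: the R amplitude is the maximum within a 1-sample
#' neighbourhood of the peak; the T-wave area is the area under the curve
#' (trapezoidal, microvolt-milliseconds) from 240 to 340 ms after the
#' R-peak. Results are averaged per condition using the block condition of
#' each beat, together with the realized heart rate and RMSSD.
#'
#' @param ecg an [EcgSignal-class] (band-passed or raw synthetic).
#' @param rTimesS R-peak times (s), e.g. from [detectRPeaks()].
#' @param conditions optional character per beat (NA beats are pooled as
#'   "all").
#' @param tWindowMs T-wave window post R (ms).
#' @return data.frame per condition: n_beats, peak_r_amplitude_uv,
#'   t_wave_area_uv_ms, mean_hr_bpm, rmssd_ms
#' @export
cardiacFeatures <- function(ecg, rTimesS = NULL, conditions = NULL,
                            tWindowMs = c(240, 340)) {
  fs <- ecg@fs
  x <- ecg@samples
  if (is.null(rTimesS)) rTimesS <- detectRPeaks(ecg)
  if (!length(rTimesS)) stop("no R-peaks supplied or detected")
  if (is.null(conditions)) conditions <- rep("all", length(rTimesS))
  conditions[is.na(conditions)] <- "all"
  idx <- round(rTimesS * fs) + 1L
  rAmp <- vapply(idx, function(i) {
    lo <- max(1L, i - 1L)
    hi <- min(length(x), i + 1L)
    max(x[lo:hi])
  }, 0)
  nT <- round(diff(tWindowMs) * fs / 1000)
  tArea <- vapply(idx, function(i) {
    j <- i + round(tWindowMs[1] * fs / 1000) + seq_len(nT) - 1L
    j <- j[j >= 1 & j <= length(x)]
    if (length(j) < 2) return(NA_real_)
    sum((x[j[-length(j)]] + x[j[-1]]) / 2) * 1000 / fs
  }, 0)
  out <- lapply(split(seq_along(idx), conditions), function(ii) {
    rr <- diff(rTimesS[sort(ii)]) * 1000
    hv <- if (length(rr) >= 2) computeHrHrv(rr) else
      c(meanHrBpm = NA_real_, rmssdMs = NA_real_)
    data.frame(condition = conditions[ii[1]], n_beats = length(ii),
               peak_r_amplitude_uv = mean(rAmp[ii]),
               t_wave_area_uv_ms = mean(tArea[ii], na.rm = TRUE),
               mean_hr_bpm = hv[["meanHrBpm"]], rmssd_ms = hv[["rmssdMs"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
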