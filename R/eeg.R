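# EEG preprocessing, epoching, artifact rejection and ROI amplitudes.
#
# Windows are half-open [start, end) ms relative to the locking event; the
# locking sample is the signal sample nearest the event time (matching the
# grid snapping used by the forward model).

#' Preprocess multichannel EEG: band-limit and average-reference
#'
#' High-pass (2nd-order Butterworth, applied forwards and backwards) to
#' remove drift, low-pass (Hamming-window FIR, zero-phase) at the upper
#' edge, then re-reference every sample to the average of all channels.
#'
#' @param eeg channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param hpHz high-pass edge (Hz); 0 disables.
#' @param lpHz low-pass edge (Hz); 0 disables.
#' @return preprocessed channels x samples matrix (channel mean is zero at
#'   every sample)
#' @export
preprocessEeg <- function(eeg, fs, hpHz = 0.1, lpHz = 40) {
  if (nrow(eeg) < 2) stop("need at least 2 channels")
  out <- eeg
  if (lpHz > 0) {
    ord <- 2L * round(0.165 * fs)       # ~10 Hz transition width
    b <- signal::fir1(ord, lpHz / (fs / 2), type = "low",
                      window = signal::hamming(ord + 1))
    for (i in seq_len(nrow(out)))
      out[i, ] <- .firFiltfilt(b, out[i, ])
  }
  if (hpHz > 0) {
    bt <- signal::butter(2, hpHz / (fs / 2), type = "high")
    for (i in seq_len(nrow(out)))
      out[i, ] <- signal::filtfilt(bt, out[i, ])
  }
  sweep(out, 2, colMeans(out))
}

#' Extract baseline-corrected epochs around events
#'
#' Slices the half-open window \code{[windowMs[1], windowMs[2])} around each
#' event (snapped to the sample grid) and subtracts, per epoch and channel,
#' the mean over the baseline window. Events whose window leaves the signal
#' support are dropped and counted in \code{nDropped}.
#'
#' @param eeg channels x samples matrix with channel rownames.
#' @param fs sampling rate (Hz).
#' @param eventTimesS event times (s).
#' @param windowMs epoch window, ms relative to the event.
#' @param baselineMs baseline window (ms); NULL skips baseline correction.
#' @param eventType label stored in the result.
#' @param info optional data.frame of per-event metadata (subset to the
#'   retained epochs).
#' @return an [EpochSet-class]; zero usable events give an empty set with a
#'   warning
#' @export
extractEpochs <- function(eeg, fs, eventTimesS, windowMs = c(-100, 1000),
                          baselineMs = c(-100, 0), eventType = "event",
                          info = NULL) {
  nCh <- nrow(eeg)
  nS <- ncol(eeg)
  nWin <- round(diff(windowMs) * fs / 1000)
  s0 <- round(windowMs[1] * fs / 1000)
  eSamp <- round(eventTimesS * fs)            # 0-based locking sample
  first <- eSamp + s0 + 1L
  last <- first + nWin - 1L
  keep <- first >= 1L & last <= nS
  nDropped <- sum(!keep)
  idxKeep <- which(keep)
  dat <- array(0, c(length(idxKeep), nCh, nWin))
  for (j in seq_along(idxKeep)) {
    i <- idxKeep[j]
    dat[j, , ] <- eeg[, first[i]:last[i]]
  }
  if (!is.null(baselineMs) && length(idxKeep)) {
    rel <- windowMs[1] + (seq_len(nWin) - 1) * 1000 / fs
    bl <- rel >= baselineMs[1] & rel < baselineMs[2]
    if (!any(bl)) stop("baseline window contains no samples")
    base <- rowMeans(dat[, , bl, drop = FALSE], dims = 2)
    dat <- dat - array(base, c(dim(base), nWin))
  }
  if (!length(idxKeep)) warning("no usable events; empty EpochSet")
  infoKeep <- if (is.null(info)) {
    data.frame(event_index = idxKeep)
  } else {
    info[idxKeep, , drop = FALSE]
  }
  rownames(infoKeep) <- NULL
  new("EpochSet", data = dat, windowMs = as.numeric(windowMs),
      baselineMs = if (is.null(baselineMs)) numeric(0) else as.numeric(baselineMs),
      eventType = eventType, fs = fs,
      channels = if (is.null(rownames(eeg))) paste0("ch", seq_len(nCh)) else rownames(eeg),
      info = infoKeep, nDropped = as.integer(nDropped))
}

#' Select the analysis events of a session for one ERP family
#'
#' Implements the segmentation rules of the design: heartbeat-locked (HEP)
#' and movement-locked (VEP/P2) epochs use only the first three qualifying
#' events before the go-cue of each trial (go-cue-free data); stop-locked
#' epochs use the stop-signal onsets; feedback-locked epochs one feedback
#' cue per trial, optionally restricted by outcome (e.g. "commission").
#'
#' @param session a [SimulatedSession-class].
#' @param family "hep", "vep", "go", "stop" or "feedback".
#' @param detail optional feedback outcome filter.
#' @param firstN events kept per trial for hep/vep.
#' @return data.frame of selected events (trial_id, condition, time_s, ...)
#' @export
selectAnalysisEvents <- function(session, family = c("hep", "vep", "go",
                                                     "stop", "feedback"),
                                 detail = NULL, firstN = 3L) {
  family <- match.arg(family)
  ev <- sessionEvents(session)
  tr <- sessionTrials(session)
  cue <- tr$go_cue_time_s[match(ev$trial_id, tr$trial_id)]
  sel <- switch(family,
    hep = ev$event_type == "r_peak" & !is.na(ev$trial_id) &
      ev$time_s < cue,
    vep = ev$event_type == "distractor_move" & !is.na(ev$trial_id) &
      ev$time_s < cue,
    go = ev$event_type == "go_cue",
    stop = ev$event_type == "stop_signal",
    feedback = ev$event_type == "feedback")
  out <- ev[which(sel), , drop = FALSE]
  if (family == "feedback" && !is.null(detail))
    out <- out[!is.na(out$detail) & out$detail == detail, , drop = FALSE]
  if (family %in% c("hep", "vep") && nrow(out)) {
    out <- do.call(rbind, lapply(split(out, out$trial_id), function(d)
      head(d[order(d$time_s), , drop = FALSE], firstN)))
  }
  rownames(out) <- NULL
  out[order(out$time_s), , drop = FALSE]
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' An epoch is removed iff any sample on any channel exceeds the threshold
#' in absolute value.
#'
#' @param epochs an [EpochSet-class].
#' @param thresholdUv rejection threshold (microvolts).
#' @return list(epochs = kept [EpochSet-class], exclusionRate = fraction
#'   removed); an all-rejected set is returned empty with a warning
#' @export
rejectEpochs <- function(epochs, thresholdUv = 100) {
  n <- length(epochs)
  if (!n) return(list(epochs = epochs, exclusionRate = NA_real_))
  x <- abs(epochs@data) > thresholdUv
  dim(x) <- c(n, prod(dim(epochs@data)[2:3]))
  bad <- rowSums(x) > 0L
  if (all(bad)) warning("all epochs rejected")
  kept <- initialize(epochs,
                     data = epochs@data[!bad, , , drop = FALSE],
                     info = epochs@info[!bad, , drop = FALSE])
  list(epochs = kept, exclusionRate = mean(bad))
}

#' Mean amplitude over an ROI (channels x time window)
#'
#' Per-epoch mean over the selected channels and the half-open time window;
#' optionally also the grand mean over epochs.
#'
#' @param epochs an [EpochSet-class].
#' @param channels character ROI channel labels.
#' @param windowMs time window (ms relative to the event).
#' @return numeric vector of per-epoch means (microvolts), with the grand
#'   mean in attribute "grandMean"
#' @export
roiMeanAmplitude <- function(epochs, channels, windowMs) {
  chIdx <- match(channels, epochs@channels)
  if (any(is.na(chIdx)))
    stop("unknown channel(s): ",
         paste(channels[is.na(chIdx)], collapse = ", "))
  rel <- epochTimesMs(epochs)
  sIdx <- which(rel >= windowMs[1] & rel < windowMs[2])
  if (!length(sIdx)) stop("window contains no samples")
  x <- epochs@data[, chIdx, sIdx, drop = FALSE]
  per <- rowMeans(x, dims = 1)
  attr(per, "grandMean") <- mean(per)
  per
}

#' Per-condition ERP average of an epoch set
#'
#' @param epochs an [EpochSet-class] whose info has a condition column.
#' @return named list of channels x samples average matrices
#' @export
erpAverage <- function(epochs) {
  stopifnot("condition" %in% names(epochs@info))
  lapply(split(seq_len(length(epochs)), epochs@info$condition), function(ii) {
    m <- colMeans(epochs@data[ii, , , drop = FALSE], dims = 1)
    rownames(m) <- epochs@channels
    m
  })
}
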