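# Timing-precision audit: realized cardiac offsets of the coupled
# distractor-movement events, audited against the offline R-peak times, as
# deviations from the intended offset (R+290 ms systole, R+0 ms diastole).

#' Audit the realized cardiac timing of coupled events
#'
#' For every distractor-movement event, computes its offset from the R-peak
#' that makes the deviation from the intended offset smallest (so a trigger
#' jittered slightly before its R-peak is scored as a small negative offset
#' rather than as the tail of the previous cycle), then summarises the
#' deviations per condition (and trial type when a trial table is given):
#' mean and SD of the realized offset, the fraction of events within
#' \code{withinMs} of the intended timing, and a histogram of realized
#' offsets in \code{binMs} bins.
#'
#' @param events session event log (needs distractor_move rows).
#' @param timeline the offline [CardiacTimeline-class].
#' @param trials optional trial table to split by trial type.
#' @param intendedOffsetsMs named numeric, intended offset per condition.
#' @param withinMs precision criterion (ms).
#' @param binMs histogram bin width (ms).
#' @return list with \code{summary} (data.frame) and \code{histograms}
#'   (named list of bin-count tables); both empty (with a warning) when no
#'   coupled events exist.
#' @export
evaluateTimingPrecision <- function(events, timeline, trials = NULL,
                                    intendedOffsetsMs = c(systole = 290,
                                                          diastole = 0),
                                    withinMs = 200, binMs = 50) {
  ev <- events[events$event_type == "distractor_move", , drop = FALSE]
  if (!nrow(ev)) {
    warning("no coupled distractor events to audit")
    return(list(summary = data.frame(), histograms = list()))
  }
  r <- rPeakTimes(timeline)
  intended <- intendedOffsetsMs[ev$condition]
  # offset relative to the preceding R, and to the R before/after it; keep
  # the candidate closest to the intended offset
  i <- findInterval(ev$time_s, r)
  cand <- cbind(prev = i, prev2 = i - 1L, nxt = i + 1L)
  offs <- matrix(NA_real_, nrow(ev), 3)
  for (k in 1:3) {
    ok <- cand[, k] >= 1 & cand[, k] <= length(r)
    offs[ok, k] <- (ev$time_s[ok] - r[cand[ok, k]]) * 1000
  }
  pick <- apply(abs(offs - intended), 1, which.min)
  offset <- offs[cbind(seq_len(nrow(ev)), pick)]
  dev <- offset - intended

  grp <- ev$condition
  if (!is.null(trials)) {
    tt <- trials$trial_type[match(ev$trial_id, trials$trial_id)]
    grp <- paste(ev$condition, tt, sep = ".")
  }
  su <- do.call(rbind, lapply(split(seq_along(grp), grp), function(ii) {
    data.frame(group = grp[ii[1]], condition = ev$condition[ii[1]],
               n = length(ii),
               mean_offset_ms = mean(offset[ii]),
               sd_offset_ms = sd(offset[ii]),
               frac_within = mean(abs(dev[ii]) <= withinMs),
               stringsAsFactors = FALSE)
  }))
  rownames(su) <- NULL
  hist <- lapply(split(offset, grp), function(x) {
    br <- seq(floor(min(x) / binMs) * binMs,
              ceiling(max(x) / binMs) * binMs + binMs, by = binMs)
    table(cut(x, br, right = FALSE))
  })
  list(summary = su, histograms = hist)
}
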