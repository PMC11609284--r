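# Trial scheduling, event generation and full-session simulation.
#
# Scheduling mirrors the task: each trial opens with an arrow display during
# which the cardiac-coupled distractors move (one movement onset per
# heartbeat at the configured offset, plus trigger-latency jitter), the
# go-cue appears 2.9-4.5 s in (with at least three heartbeats before it),
# stop trials add the staircase-tracked SSD, feedback follows the fixed
# 1.5 s response window, and a 0.5 s inter-trial interval closes the trial.

#' Plan a single trial on the cardiac timeline
#'
#' Places the go-cue uniformly in the pre-cue window subject to the
#' heartbeat-count constraint (redrawing up to \code{maxRetries} times; if
#' the constraint is still unmet the window is extended to the third beat
#' plus 50 ms and the trial flagged), generates one distractor-movement
#' onset per pre-cue heartbeat at the condition's cardiac offset with
#' Gaussian trigger-latency jitter, and fixes the stop-signal and feedback
#' times. Uses the current RNG stream.
#'
#' @param timeline a [CardiacTimeline-class] covering the trial.
#' @param tStartS trial start time (s).
#' @param condition "systole", "diastole" or "none".
#' @param trialType "go" or "stop".
#' @param ssdMs staircase SSD for stop trials (ms).
#' @param config a [SessionConfig-class].
#' @param maxRetries resampling budget for the cue placement.
#' @return list with goCueTimeS, stopTimeS (NA on go trials),
#'   feedbackTimeS, trialEndS, distractorTimesS, nPrecueBeats, extended
#' @export
planTrial <- function(timeline, tStartS, condition, trialType, ssdMs,
                      config, maxRetries = 100L) {
  r <- rPeakTimes(timeline)
  win <- config@preCueWindowS
  if (tStartS + win[2] > r[length(r)])
    stop("cardiac timeline too short for this trial")
  nBeatsBefore <- function(cue) sum(r >= tStartS & r < cue)
  cue <- NA_real_
  extended <- FALSE
  for (k in seq_len(maxRetries)) {
    cand <- tStartS + runif(1, win[1], win[2])
    nb <- nBeatsBefore(cand)
    if (nb >= config@minHeartbeatsPreCue && nb <= config@maxHeartbeatsPreCue) {
      cue <- cand
      break
    }
  }
  if (is.na(cue)) {
    # slow heart: extend the window to the third beat + 50 ms and flag
    inWin <- r[r >= tStartS]
    if (length(inWin) < config@minHeartbeatsPreCue)
      stop("cardiac timeline too short for this trial")
    cue <- inWin[config@minHeartbeatsPreCue] + 0.05
    extended <- TRUE
  }
  preBeats <- r[r >= tStartS & r < cue]
  distractor <- numeric(0)
  if (condition != "none") {
    off <- if (condition == "systole") config@systoleOffsetMs else config@diastoleOffsetMs
    jit <- rnorm(length(preBeats), 0, config@triggerJitterSdMs)
    distractor <- preBeats + (off + jit) / 1000
  }
  stopTime <- if (trialType == "stop") cue + ssdMs / 1000 else NA_real_
  feedback <- cue + config@goDisplayS
  list(goCueTimeS = cue, stopTimeS = stopTime, feedbackTimeS = feedback,
       trialEndS = feedback + config@feedbackDisplayS,
       distractorTimesS = distractor, nPrecueBeats = length(preBeats),
       extended = extended)
}

# cardiac offset (ms since preceding R-peak) for event times; NA before the
# first R-peak
cardiacOffsetMs <- function(timesS, timeline) {
  r <- rPeakTimes(timeline)
  i <- findInterval(timesS, r)
  off <- rep(NA_real_, length(timesS))
  ok <- i >= 1
  off[ok] <- (timesS[ok] - r[i[ok]]) * 1000
  off
}

#' Render multichannel EEG from an event log and templates
#'
#' Linear forward model: the signal is the superposition of every
#' event-locked template (scaled by its condition gain), plus white sensor
#' noise. Event times are snapped to the sample grid, so with zero noise the
#' event-locked average equals the injected template exactly. Events whose
#' template support leaves the signal are skipped with a message.
#'
#' @param events data.frame with columns event_type, detail, time_s,
#'   condition.
#' @param templates list of [ErpTemplate-class] (include the CFA template
#'   here to add the cardiac field artifact).
#' @param montage montage data.frame; channel order of the output.
#' @param fs sampling rate (Hz).
#' @param durationS signal length (s).
#' @param noiseSd white noise SD (microvolts).
#' @param seed optional integer seed.
#' @param returnSources if TRUE, also return per-template source time
#'   courses and the mixing matrix of the forward model.
#' @return channels x samples matrix, or list(eeg, sources, mixing) when
#'   \code{returnSources = TRUE}
#' @export
renderEeg <- function(events, templates, montage, fs, durationS,
                      noiseSd = 0, seed = NULL, returnSources = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  labels <- montage$label
  nCh <- length(labels)
  nS <- ceiling(durationS * fs)
  sources <- matrix(0, length(templates), nS,
                    dimnames = list(names(templates), NULL))
  mixing <- matrix(0, nCh, length(templates),
                   dimnames = list(labels, names(templates)))
  nSkipped <- 0L
  for (k in seq_along(templates)) {
    tpl <- templates[[k]]
    w <- tpl@channelWeights[labels]
    if (any(is.na(w)))
      stop("template ", tpl@name, " lacks weights for some montage channels")
    mixing[, k] <- w
    sel <- events$event_type == tpl@eventType
    if (!is.na(tpl@eventDetail))
      sel <- sel & !is.na(events$detail) & events$detail == tpl@eventDetail
    ev <- events[sel, , drop = FALSE]
    nWin <- round(diff(tpl@windowMs) * fs / 1000)
    for (j in seq_len(nrow(ev))) {
      eSamp <- round(ev$time_s[j] * fs)            # snap to grid (0-based)
      i1 <- eSamp + ceiling(tpl@windowMs[1] * fs / 1000) + 1L
      idx <- i1:(i1 + nWin - 1L)
      if (idx[1] < 1L || idx[nWin] > nS) {
        nSkipped <- nSkipped + 1L
        next
      }
      latMs <- ((idx - 1L) - eSamp) * 1000 / fs
      gain <- templateGain(tpl, ev$condition[j])
      if (is.na(gain)) gain <- 1
      sources[k, idx] <- sources[k, idx] + templateWaveform(tpl, latMs) * gain
    }
  }
  if (nSkipped)
    message(nSkipped, " events outside signal support were skipped")
  eeg <- mixing %*% sources
  if (noiseSd > 0)
    eeg <- eeg + matrix(rnorm(nCh * nS, 0, noiseSd), nCh, nS)
  rownames(eeg) <- labels
  if (returnSources) list(eeg = eeg, sources = sources, mixing = mixing)
  else eeg
}

#' Simulate a full experimental session
#'
#' Generates the cardiac timeline, schedules every trial block-wise with a
#' separate staircase per condition, lets the race-model agent behave,
#' synthesizes the ECG, and (optionally) renders 64-channel EEG containing
#' the injected ERP templates, the R-locked cardiac field artifact and
#' sensor noise. Ground truth (templates, gains, mixing, sources) is stored
#' for downstream validation.
#'
#' @param config a [SessionConfig-class].
#' @param seed integer seed; overrides \code{config@seed} when given.
#' @param withEeg render the EEG forward model (set FALSE for
#'   behaviour-only simulations, which are much lighter).
#' @return a [SimulatedSession-class]
#' @examples
#' cfg <- sessionConfigNew(trialsPerBlock = 6L, goPerBlock = 4L,
#'                         stopPerBlock = 2L, eegFs = 250)
#' ses <- simulateSession(cfg, seed = 1, withEeg = FALSE)
#' table(sessionTrials(ses)$condition, sessionTrials(ses)$trial_type)
#' @export
simulateSession <- function(config, seed = NULL, withEeg = TRUE) {
  if (is.null(seed)) seed <- config@seed
  set.seed(seed)
  conds <- config@conditions[config@blockOrder]
  nTrials <- length(conds) * config@trialsPerBlock
  # conservative duration bound: every trial at its maximum length
  maxTrial <- config@preCueWindowS[2] + config@goDisplayS +
    config@feedbackDisplayS + config@itiS
  durEst <- nTrials * maxTrial + 10
  nBeats <- ceiling(durEst / 60 * config@meanHrBpm * 1.3) + 20
  timeline <- simulateRRSeries(config@meanHrBpm, config@rmssdMs, nBeats,
                               t0 = 0.5)
  montage <- standardMontage(config@montageId)

  stair <- lapply(config@conditions, function(cc)
    staircaseState(baseMs = config@staircaseBaseMs,
                   stepMs = config@staircaseStepMs,
                   maxMs = config@staircaseMaxMs,
                   floorMs = config@staircaseFloorMs, condition = cc))
  names(stair) <- config@conditions

  trials <- vector("list", nTrials)
  events <- vector("list", nTrials)
  tCur <- 1.0
  tid <- 0L
  for (b in seq_along(conds)) {
    cond <- conds[b]
    seq0 <- sample(c(rep("go", config@goPerBlock),
                     rep("stop", config@stopPerBlock)))
    for (tt in seq0) {
      tid <- tid + 1L
      curSsd <- if (tt == "stop") stair[[cond]]@ssdMs else NA_real_
      plan <- planTrial(timeline, tCur, cond, tt, curSsd, config)
      out <- sampleRaceOutcome(config@race,
                               ssdMs = if (tt == "stop") curSsd else NA,
                               trialType = tt,
                               goDisplayMs = config@goDisplayS * 1000)
      if (tt == "stop")
        stair[[cond]] <- updateStaircase(stair[[cond]], out$responded)
      correct <- if (tt == "go") out$responded else !out$responded
      detail <- if (tt == "go") {
        if (out$responded) "hit" else "miss"
      } else {
        if (out$responded) "commission" else "rejection"
      }
      evType <- c("go_cue", if (tt == "stop") "stop_signal",
                  if (out$responded) "response", "feedback")
      evTime <- c(plan$goCueTimeS, if (tt == "stop") plan$stopTimeS,
                  if (out$responded) plan$goCueTimeS + out$rtMs / 1000,
                  plan$feedbackTimeS)
      evDetail <- c(NA_character_, if (tt == "stop") NA_character_,
                    if (out$responded) NA_character_, detail)
      if (length(plan$distractorTimesS)) {
        evType <- c(rep("distractor_move", length(plan$distractorTimesS)), evType)
        evTime <- c(plan$distractorTimesS, evTime)
        evDetail <- c(rep(NA_character_, length(plan$distractorTimesS)), evDetail)
      }
      o <- order(evTime)
      events[[tid]] <- data.frame(
        trial_id = tid, block = b, condition = cond,
        event_type = evType[o], detail = evDetail[o], time_s = evTime[o],
        stringsAsFactors = FALSE)
      trials[[tid]] <- data.frame(
        trial_id = tid, block = b, condition = cond, trial_type = tt,
        trial_start_s = tCur, go_cue_time_s = plan$goCueTimeS,
        ssd_ms = curSsd, responded = out$responded, rt_ms = out$rtMs,
        correct = correct, feedback = detail,
        feedback_time_s = plan$feedbackTimeS,
        n_precue_beats = plan$nPrecueBeats, extended = plan$extended,
        trial_length_s = plan$trialEndS - tCur,
        stringsAsFactors = FALSE)
      tCur <- plan$trialEndS + config@itiS
    }
  }
  events <- do.call(rbind, events)
  trials <- do.call(rbind, trials)
  sessionEndS <- tCur + 1

  # every heartbeat in the session span is an event (the heart does not
  # pause between trials); beats inside a trial inherit its id, beats
  # inside a block (e.g. during the inter-trial interval) its condition
  rAll <- rPeakTimes(timeline)
  rAll <- rAll[rAll < sessionEndS]
  ti <- findInterval(rAll, trials$trial_start_s)
  inTrial <- ti >= 1 &
    rAll < (trials$trial_start_s + trials$trial_length_s)[pmax(ti, 1L)]
  bi <- findInterval(rAll, tapply(trials$trial_start_s, trials$block, min))
  inBlock <- bi >= 1
  rEvents <- data.frame(
    trial_id = ifelse(inTrial, trials$trial_id[pmax(ti, 1L)], NA_integer_),
    block = ifelse(inBlock, bi, NA_integer_),
    condition = ifelse(inBlock, conds[pmax(bi, 1L)], NA_character_),
    event_type = "r_peak", detail = NA_character_, time_s = rAll,
    stringsAsFactors = FALSE)
  events <- rbind(events, rEvents)
  events <- events[order(events$time_s), ]
  rownames(events) <- NULL
  events$cardiac_offset_ms <- cardiacOffsetMs(events$time_s, timeline)

  # trim the timeline to the session span (plus padding)
  keep <- rPeakTimes(timeline) <= sessionEndS + 2
  rr <- rrIntervals(timeline)[head(which(keep), -1)]
  timeline <- cardiacTimeline(rr, t0 = rPeakTimes(timeline)[1])

  ecg <- synthesizeEcg(timeline, fs = config@ecgFs)

  gains <- do.call(rbind, lapply(names(config@templates), function(nm) {
    tp <- config@templates[[nm]]
    data.frame(template = nm, condition = config@conditions,
               gain = templateGain(tp, config@conditions))
  }))
  gt <- list(templates = config@templates, gains = gains, seed = seed)

  eeg <- matrix(numeric(0), 0, 0)
  if (withEeg) {
    rTpls <- config@templates
    if (config@cfaAmplitude > 0)
      rTpls$CFA <- defaultCfaTemplate(montage, config@cfaAmplitude)
    rend <- renderEeg(events, rTpls, montage, fs = config@eegFs,
                      durationS = sessionEndS, noiseSd = config@noiseSd,
                      returnSources = TRUE)
    eeg <- rend$eeg
    gt$mixing <- rend$mixing
    gt$sources <- rend$sources
  }

  new("SimulatedSession", config = config, timeline = timeline, ecg = ecg,
      eeg = eeg, montage = montage, events = events, trials = trials,
      groundTruth = gt)
}
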