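# SessionConfig construction and (de)serialisation. All study design
# constants live here; the YAML config dialect mirrors the constructor
# arguments one-to-one.

#' Construct a session configuration
#'
#' Defaults are the study design constants: 3 blocks of 150 trials
#' (100 go / 50 stop), one block per condition (systole-coupled,
#' diastole-coupled, no-distractor), go-cue 2.9-4.5 s into the trial after
#' at least three heartbeats, 1.5 s go response window, 1 s stop display,
#' 1 s feedback, 0.5 s inter-trial interval, staircase 200/50/750 ms
#' (floor 50 ms), distractor coupling at R+290 ms / R+0 ms with 70 ms
#' trigger-latency jitter, mean heart rate 58.2 bpm with RMSSD 53.5 ms, and
#' white sensor noise with SD 10 microvolts.
#'
#' @param conditions condition per block.
#' @param blockOrder permutation of the conditions giving presentation
#'   order (counterbalance selector).
#' @param trialsPerBlock,goPerBlock,stopPerBlock trial counts per block.
#' @param preCueWindowS go-cue placement window (s after trial start).
#' @param minHeartbeatsPreCue,maxHeartbeatsPreCue heartbeat constraints on
#'   the pre-cue window.
#' @param goDisplayS,stopDisplayS,feedbackDisplayS,itiS display durations (s).
#' @param systoleOffsetMs,diastoleOffsetMs intended distractor-movement
#'   offsets from the R-peak (ms).
#' @param triggerJitterSdMs SD of the Gaussian trigger-latency jitter (ms).
#' @param staircaseBaseMs,staircaseStepMs,staircaseMaxMs,staircaseFloorMs
#'   staircase constants (ms).
#' @param meanHrBpm,rmssdMs cardiac process parameters.
#' @param race a [RaceModelParams-class] for the behaving agent.
#' @param montageId packaged montage identifier.
#' @param noiseSd EEG sensor noise SD (microvolts).
#' @param ecgFs,eegFs sampling rates (Hz).
#' @param templates list of [ErpTemplate-class]; NULL = defaults for the
#'   montage (HEP, P2, N2, P3).
#' @param cfaAmplitude cardiac-field-artifact peak amplitude (microvolts);
#'   0 disables the artifact.
#' @param seed integer seed recorded in the config.
#' @return a [SessionConfig-class]
#' @export
sessionConfigNew <- function(conditions = c("systole", "diastole", "none"),
                             blockOrder = seq_along(conditions),
                             trialsPerBlock = 150L, goPerBlock = 100L,
                             stopPerBlock = 50L,
                             preCueWindowS = c(2.9, 4.5),
                             minHeartbeatsPreCue = 3L,
                             maxHeartbeatsPreCue = 5L,
                             goDisplayS = 1.5, stopDisplayS = 1.0,
                             feedbackDisplayS = 1.0, itiS = 0.5,
                             systoleOffsetMs = 290, diastoleOffsetMs = 0,
                             triggerJitterSdMs = 70,
                             staircaseBaseMs = 200, staircaseStepMs = 50,
                             staircaseMaxMs = 750, staircaseFloorMs = 50,
                             meanHrBpm = 58.2, rmssdMs = 53.5,
                             race = raceModelParams(omissionRate = 0.08),
                             montageId = "montage_64_1010", noiseSd = 10,
                             ecgFs = 500, eegFs = 500,
                             templates = NULL, cfaAmplitude = 15,
                             seed = 1L) {
  if (is.null(templates))
    templates <- defaultErpTemplates(standardMontage(montageId))
  new("SessionConfig", conditions = conditions,
      blockOrder = as.integer(blockOrder),
      trialsPerBlock = as.integer(trialsPerBlock),
      goPerBlock = as.integer(goPerBlock),
      stopPerBlock = as.integer(stopPerBlock),
      preCueWindowS = preCueWindowS,
      minHeartbeatsPreCue = as.integer(minHeartbeatsPreCue),
      maxHeartbeatsPreCue = as.integer(maxHeartbeatsPreCue),
      goDisplayS = goDisplayS, stopDisplayS = stopDisplayS,
      feedbackDisplayS = feedbackDisplayS, itiS = itiS,
      systoleOffsetMs = systoleOffsetMs, diastoleOffsetMs = diastoleOffsetMs,
      triggerJitterSdMs = triggerJitterSdMs,
      staircaseBaseMs = staircaseBaseMs, staircaseStepMs = staircaseStepMs,
      staircaseMaxMs = staircaseMaxMs, staircaseFloorMs = staircaseFloorMs,
      meanHrBpm = meanHrBpm, rmssdMs = rmssdMs, race = race,
      montageId = montageId, noiseSd = noiseSd, ecgFs = ecgFs, eegFs = eegFs,
      templates = templates, cfaAmplitude = cfaAmplitude,
      seed = as.integer(seed))
}

# scalar config fields serialised to/from YAML (templates and race are
# handled separately)
.configScalarFields <- c("conditions", "blockOrder", "trialsPerBlock",
  "goPerBlock", "stopPerBlock", "preCueWindowS", "minHeartbeatsPreCue",
  "maxHeartbeatsPreCue", "goDisplayS", "stopDisplayS", "feedbackDisplayS",
  "itiS", "systoleOffsetMs", "diastoleOffsetMs", "triggerJitterSdMs",
  "staircaseBaseMs", "staircaseStepMs", "staircaseMaxMs", "staircaseFloorMs",
  "meanHrBpm", "rmssdMs", "montageId", "noiseSd", "ecgFs", "eegFs",
  "cfaAmplitude", "seed")

#' Write a session configuration to a YAML file
#' @param config a [SessionConfig-class].
#' @param path output file.
#' @export
writeSessionConfig <- function(config, path) {
  x <- lapply(.configScalarFields, function(f) slot(config, f))
  names(x) <- .configScalarFields
  x$race <- list(goMu = config@race@goMu, goSigma = config@race@goSigma,
                 goTau = config@race@goTau, ssrtTrue = config@race@ssrtTrue,
                 omissionRate = config@race@omissionRate)
  x$templateGains <- lapply(config@templates, function(tp)
    as.list(tp@conditionGains))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a session configuration from a YAML file
#'
#' Any key omitted from the file keeps its default; \code{...} overrides
#' take final precedence (the command-line override mechanism).
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param ... named overrides of constructor arguments.
#' @return a [SessionConfig-class]
#' @export
readSessionConfig <- function(path = NULL, ...) {
  x <- if (is.null(path)) list() else yaml::read_yaml(path)
  overrides <- list(...)
  args <- x[names(x) %in% .configScalarFields]
  if (!is.null(x$race)) args$race <- do.call(raceModelParams, x$race)
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  cfg <- do.call(sessionConfigNew, args)
  # per-template condition gains may be overridden from the file
  if (!is.null(x$templateGains)) {
    for (nm in names(x$templateGains)) {
      if (nm %in% names(cfg@templates)) {
        g <- unlist(x$templateGains[[nm]])
        cfg@templates[[nm]]@conditionGains[names(g)] <- g
      }
    }
  }
  validObject(cfg)
  cfg
}
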