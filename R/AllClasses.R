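# S4 containers for the simulation and analysis pipeline.
#
# Sample indexing convention: R storage is 1-based as usual, but all
# epoch/time windows are half-open [start, end) in milliseconds relative to
# the locking event, so a window of (end - start) ms at sampling rate fs
# always holds exactly (end - start) * fs / 1000 samples.

#' CardiacTimeline: R-peak times and RR intervals
#'
#' The clock every cardiac-coupled event references. Holds R-peak times (s),
#' the RR intervals between them (ms) and a per-beat estimate of the end of
#' the T wave (ms after the R-peak), used to split each cardiac cycle into
#' systole (R to T-end) and diastole (T-end to next R).
#'
#' @slot rPeakTimes numeric, strictly increasing R-peak times in seconds.
#' @slot rrIntervals numeric, RR intervals in ms; length is one less than
#'   the number of R-peaks and equals \code{diff(rPeakTimes) * 1000}.
#' @slot tEndOffsets numeric, per-beat end-of-T estimate in ms after the
#'   R-peak; always shorter than the beat's RR interval.
#' @export
setClass("CardiacTimeline",
  representation(rPeakTimes = "numeric",
                 rrIntervals = "numeric",
                 tEndOffsets = "numeric"))

setValidity("CardiacTimeline", function(object) {
  r <- object@rPeakTimes
  rr <- object@rrIntervals
  te <- object@tEndOffsets
  if (length(r) < 1L) return("need at least one R-peak")
  if (length(r) > 1L && any(diff(r) <= 0)) return("rPeakTimes must be strictly increasing")
  if (length(rr) != length(r) - 1L) return("rrIntervals must have length(rPeakTimes) - 1")
  if (length(rr) && max(abs(rr - diff(r) * 1000)) > 1e-6)
    return("rrIntervals inconsistent with rPeakTimes (tolerance 1e-6 ms)")
  if (length(te) != length(r)) return("tEndOffsets must have one value per beat")
  if (length(rr) && any(te[seq_along(rr)] >= rr))
    return("tEndOffsets must be shorter than the corresponding RR interval")
  TRUE
})

#' EcgSignal: a sampled ECG trace with ground-truth R-peak locations
#'
#' @slot samples numeric, the trace in microvolts.
#' @slot fs numeric, sampling rate in Hz.
#' @slot trueRIndices integer, 1-based sample indices of the true R-peaks
#'   (known for synthetic traces; empty for externally supplied data).
#' @export
setClass("EcgSignal",
  representation(samples = "numeric", fs = "numeric",
                 trueRIndices = "integer"))

setValidity("EcgSignal", function(object) {
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a single positive number")
  if (length(object@trueRIndices) &&
      (min(object@trueRIndices) < 1L ||
       max(object@trueRIndices) > length(object@samples)))
    return("trueRIndices out of bounds")
  TRUE
})

#' RaceModelParams: independent-race agent parameters
#'
#' Go finishing times are ex-Gaussian (Gaussian mu/sigma plus exponential
#' tau); the stop finishing time (the true SSRT) is a constant. On a stop
#' trial the agent responds iff its go process finishes before SSD + SSRT.
#'
#' @slot goMu,goSigma,goTau numeric, ex-Gaussian go finishing time (ms).
#' @slot ssrtTrue numeric, stop finishing time (ms).
#' @slot omissionRate numeric in [0, 1], probability of failing to respond
#'   on a go trial irrespective of the finishing time.
#' @export
setClass("RaceModelParams",
  representation(goMu = "numeric", goSigma = "numeric", goTau = "numeric",
                 ssrtTrue = "numeric", omissionRate = "numeric"))

setValidity("RaceModelParams", function(object) {
  if (any(c(object@goMu, object@goSigma, object@goTau, object@ssrtTrue) <= 0))
    return("goMu, goSigma, goTau and ssrtTrue must be positive")
  if (object@omissionRate < 0 || object@omissionRate > 1)
    return("omissionRate must be in [0, 1]")
  TRUE
})

#' ErpTemplate: an event-locked scalp component for the forward model
#'
#' A template is a single spatial pattern (per-channel gains) times a
#' time-limited waveform locked to events of one type, optionally restricted
#' by the event's detail field (e.g. commission feedback only). Condition
#' gains scale the waveform per experimental condition; the waveform is zero
#' outside its latency window.
#'
#' @slot name character label (e.g. "HEP", "P2").
#' @slot eventType event type the template locks to
#'   (r_peak, distractor_move, go_cue, stop_signal, feedback).
#' @slot eventDetail optional detail filter (e.g. "commission"); NA for none.
#' @slot windowMs numeric length-2, latency support in ms post event.
#' @slot amplitude numeric, peak amplitude in microvolts (sign carries
#'   polarity, e.g. negative for an N2).
#' @slot shape waveform shape within the window: "hann" or "square".
#' @slot channelWeights named numeric, per-channel gain in [0 - 1] scale.
#' @slot conditionGains named numeric multiplier per condition; conditions
#'   absent from the vector default to gain 1.
#' @export
setClass("ErpTemplate",
  representation(name = "character", eventType = "character",
                 eventDetail = "character", windowMs = "numeric",
                 amplitude = "numeric", shape = "character",
                 channelWeights = "numeric", conditionGains = "numeric"))

setValidity("ErpTemplate", function(object) {
  if (length(object@windowMs) != 2L || diff(object@windowMs) <= 0)
    return("windowMs must be an increasing length-2 window")
  if (!all(is.finite(object@channelWeights)))
    return("channelWeights must be finite")
  if (!object@shape %in% c("hann", "square", "qrst"))
    return("shape must be 'hann', 'square' or 'qrst'")
  TRUE
})

#' SessionConfig: every design constant of a simulated session
#'
#' Defaults reproduce the study design: 3 blocks (systole-coupled,
#' diastole-coupled, no-distractor) of 150 trials (100 go / 50 stop), go-cue
#' 2.9-4.5 s into the trial after at least three heartbeats, 1.5 s response
#' window, 1 s stop-signal display, 1 s feedback, 0.5 s inter-trial
#' interval, staircase 200/50/750 ms, distractor coupling at R+290 ms
#' (systole) and R+0 ms (diastole) with 70 ms trigger-latency jitter, and a
#' cardiac process with mean heart rate 58.2 bpm and RMSSD 53.5 ms.
#'
#' @export
setClass("SessionConfig",
  representation(conditions = "character", blockOrder = "integer",
                 trialsPerBlock = "integer", goPerBlock = "integer",
                 stopPerBlock = "integer",
                 preCueWindowS = "numeric", minHeartbeatsPreCue = "integer",
                 maxHeartbeatsPreCue = "integer",
                 goDisplayS = "numeric", stopDisplayS = "numeric",
                 feedbackDisplayS = "numeric", itiS = "numeric",
                 systoleOffsetMs = "numeric", diastoleOffsetMs = "numeric",
                 triggerJitterSdMs = "numeric",
                 staircaseBaseMs = "numeric", staircaseStepMs = "numeric",
                 staircaseMaxMs = "numeric", staircaseFloorMs = "numeric",
                 meanHrBpm = "numeric", rmssdMs = "numeric",
                 race = "RaceModelParams",
                 montageId = "character", noiseSd = "numeric",
                 ecgFs = "numeric", eegFs = "numeric",
                 templates = "list", cfaAmplitude = "numeric",
                 seed = "integer"))

setValidity("SessionConfig", function(object) {
  if (object@goPerBlock + object@stopPerBlock != object@trialsPerBlock)
    return("goPerBlock + stopPerBlock must equal trialsPerBlock")
  if (!length(object@conditions)) return("need at least one condition")
  if (!all(object@conditions %in% c("systole", "diastole", "none")))
    return("conditions must be among systole, diastole, none")
  if (length(object@blockOrder) != length(object@conditions) ||
      !setequal(object@blockOrder, seq_along(object@conditions)))
    return("blockOrder must be a permutation of the condition indices")
  if (length(object@preCueWindowS) != 2L || diff(object@preCueWindowS) <= 0 ||
      any(object@preCueWindowS <= 0))
    return("preCueWindowS must be a positive increasing window")
  durs <- c(object@goDisplayS, object@stopDisplayS, object@feedbackDisplayS,
            object@itiS)
  if (any(durs <= 0)) return("all display durations must be positive")
  if (object@staircaseFloorMs > object@staircaseBaseMs ||
      object@staircaseBaseMs > object@staircaseMaxMs)
    return("need staircaseFloorMs <= staircaseBaseMs <= staircaseMaxMs")
  TRUE
})

#' SimulatedSession: one fully synthetic experimental session
#'
#' @slot config the [SessionConfig-class] used.
#' @slot timeline the [CardiacTimeline-class] covering the session.
#' @slot ecg the synthetic [EcgSignal-class].
#' @slot eeg numeric matrix (channels x samples, microvolts) or a 0x0 matrix
#'   when the session was simulated without EEG rendering.
#' @slot montage data.frame with columns label, x_cm, y_cm, z_cm.
#' @slot events data.frame event log (trial_id, block, condition,
#'   event_type, detail, time_s, cardiac_offset_ms).
#' @slot trials data.frame, one row per trial.
#' @slot groundTruth list with the injected templates, their per-condition
#'   gains, and (when EEG was rendered) the mixing matrix and source time
#'   courses of the forward model.
#' @export
setClass("SimulatedSession",
  representation(config = "SessionConfig", timeline = "CardiacTimeline",
                 ecg = "EcgSignal", eeg = "matrix", montage = "data.frame",
                 events = "data.frame", trials = "data.frame",
                 groundTruth = "list"))

#' StaircaseState: one condition's adaptive SSD tracker
#'
#' @slot ssdMs current stop-signal delay (ms).
#' @slot baseMs,stepMs,maxMs,floorMs staircase constants (ms).
#' @slot condition condition label the tracker belongs to.
#' @export
setClass("StaircaseState",
  representation(ssdMs = "numeric", baseMs = "numeric", stepMs = "numeric",
                 maxMs = "numeric", floorMs = "numeric",
                 condition = "character"))

setValidity("StaircaseState", function(object) {
  if (object@ssdMs < object@floorMs || object@ssdMs > object@maxMs)
    return("ssdMs outside [floorMs, maxMs]")
  TRUE
})

#' EpochSet: epochs x channels x samples with window and baseline metadata
#'
#' The unit of all ERP computation. Epoch windows are half-open
#' \code{[start, end)} ms relative to the locking event, so the sample count
#' is exactly \code{(end - start) * fs / 1000}. Baseline correction
#' subtracts, per epoch and channel, the mean over the baseline window.
#'
#' @slot data numeric array, epochs x channels x samples (microvolts).
#' @slot windowMs,baselineMs length-2 windows in ms relative to the event.
#' @slot eventType character, the locking event type.
#' @slot fs sampling rate (Hz).
#' @slot channels character, channel labels (second array dimension).
#' @slot info data.frame of per-epoch metadata (condition, trial_id, ...).
#' @slot nDropped number of events dropped because their window left the
#'   signal support.
#' @export
setClass("EpochSet",
  representation(data = "array", windowMs = "numeric", baselineMs = "numeric",
                 eventType = "character", fs = "numeric",
                 channels = "character", info = "data.frame",
                 nDropped = "integer"))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be epochs x channels x samples")
  if (d[2] != length(object@channels)) return("channel labels do not match data")
  if (d[1] != nrow(object@info)) return("info must have one row per epoch")
  ns <- round(diff(object@windowMs) * object@fs / 1000)
  if (d[3] != ns)
    return(sprintf("sample count %d != (end-start)*fs/1000 = %d", d[3], ns))
  TRUE
})

#' CfaEstimate: cardiac-field-artifact templates from random triggers
#'
#' Per phase (systole, diastole): the trigger-locked channels x samples
#' average over (-1000, 2000) ms around the random triggers (baseline-
#' corrected over the 100 ms before the trigger), plus a re-aligned R-locked
#' average of the same segments used for subtraction.
#'
#' @slot triggerLocked,rLocked named lists (systole, diastole) of channels x
#'   samples matrices; R-locked templates span \code{rWindowMs}.
#' @slot windowMs,rWindowMs template windows (ms relative to trigger / R).
#' @slot fs sampling rate (Hz).
#' @slot channels channel labels.
#' @slot nTriggers named integer, triggers used per phase.
#' @export
setClass("CfaEstimate",
  representation(triggerLocked = "list", rLocked = "list",
                 windowMs = "numeric", rWindowMs = "numeric", fs = "numeric",
                 channels = "character", nTriggers = "integer"))

#' ComponentSet: a linear decomposition of multichannel EEG
#'
#' Channels-x-components mixing weights and component source time courses,
#' with optional per-component ECG coherence scores and rank order. The
#' decomposition is lossless: mixing %*% sources reconstructs the input.
#'
#' @slot sources numeric matrix, components x samples.
#' @slot mixing numeric matrix, channels x components.
#' @slot fs sampling rate (Hz).
#' @slot channels channel labels.
#' @slot componentNames character labels per component.
#' @slot coherence numeric per component (NA before ranking; NA for
#'   degenerate constant components).
#' @slot rankOrder integer permutation, most ECG-coherent first (length 0
#'   before ranking).
#' @export
setClass("ComponentSet",
  representation(sources = "matrix", mixing = "matrix", fs = "numeric",
                 channels = "character", componentNames = "character",
                 coherence = "numeric", rankOrder = "integer"))

setValidity("ComponentSet", function(object) {
  if (ncol(object@mixing) != nrow(object@sources))
    return("mixing columns must match source rows")
  if (nrow(object@mixing) != length(object@channels))
    return("channel labels do not match mixing rows")
  TRUE
})

#' AdjacencyGraph: spatial neighbour structure of an electrode montage
#'
#' @slot labels channel labels.
#' @slot coords numeric matrix (channels x 3), head-centered cm.
#' @slot edges integer matrix (2 columns) of neighbour index pairs, i < j.
#' @slot thresholdCm distance threshold that defined the edges.
#' @export
setClass("AdjacencyGraph",
  representation(labels = "character", coords = "matrix",
                 edges = "matrix", thresholdCm = "numeric"))

setValidity("AdjacencyGraph", function(object) {
  if (nrow(object@coords) != length(object@labels))
    return("coords must have one row per label")
  if (ncol(object@edges) && nrow(object@edges)) {
    if (any(object@edges[, 1] == object@edges[, 2])) return("self-edges not allowed")
    if (max(object@edges) > length(object@labels)) return("edge index out of bounds")
  }
  TRUE
})

#' ClusterResult: spatiotemporal cluster-based permutation test output
#'
#' @slot clusters list of data.frames (channel, sample) giving each
#'   cluster's members.
#' @slot summedT numeric, summed t statistic per cluster.
#' @slot pValues numeric, Monte-Carlo (or exhaustive) p per cluster.
#' @slot significant logical, p <= alpha.
#' @slot tMap observed t matrix (channels x samples).
#' @slot threshold cluster-forming |t| threshold used.
#' @slot alpha significance level.
#' @slot nPermutations permutations used (2^n when exhaustive).
#' @slot exhaustive logical, whether all sign assignments were enumerated.
#' @slot channels,timesMs axis labels of tMap.
#' @export
setClass("ClusterResult",
  representation(clusters = "list", summedT = "numeric", pValues = "numeric",
                 significant = "logical", tMap = "matrix",
                 threshold = "numeric", alpha = "numeric",
                 nPermutations = "integer", exhaustive = "logical",
                 channels = "character", timesMs = "numeric"))

setValidity("ClusterResult", function(object) {
  k <- length(object@clusters)
  if (length(object@summedT) != k || length(object@pValues) != k)
    return("summedT and pValues must match the number of clusters")
  if (k && min(object@pValues) < 1 / (object@nPermutations + 1) - 1e-12)
    return("p-values below 1/(nPermutations + 1)")
  TRUE
})

#' EffectEstimate: mixed-model condition-effect estimates
#'
#' @slot coefficients data.frame with estimate, se, df, t, p per fixed
#'   effect.
#' @slot ranefVar numeric, subject random-intercept variance.
#' @slot formula character, model formula fitted.
#' @slot aic named numeric, AIC of the candidate models compared.
#' @slot singular logical, whether the fit was singular.
#' @slot fallback logical, TRUE when a singular fit was replaced by
#'   within-subject paired contrasts.
#' @slot fit the underlying model object (or NULL).
#' @export
setClass("EffectEstimate",
  representation(coefficients = "data.frame", ranefVar = "numeric",
                 formula = "character", aic = "numeric",
                 singular = "logical", fallback = "logical", fit = "ANY"))
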