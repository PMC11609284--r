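setMethod("show", "CardiacTimeline", function(object) {
  n <- length(object@rPeakTimes)
  cat("CardiacTimeline with", n, "R-peaks spanning",
      sprintf("%.1f s", diff(range(object@rPeakTimes))), "\n")
  if (n > 1) {
    hv <- computeHrHrv(object@rrIntervals)
    cat(sprintf("  mean HR %.1f bpm, RMSSD %.1f ms\n", hv[["meanHrBpm"]],
                hv[["rmssdMs"]]))
  }
})

setMethod("show", "EcgSignal", function(object) {
  cat(sprintf("EcgSignal: %d samples @ %g Hz (%.1f s), %d known R-peaks\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              length(object@trueRIndices)))
})

setMethod("show", "SessionConfig", function(object) {
  cat("SessionConfig:", length(object@conditions), "blocks x",
      object@trialsPerBlock, "trials (", object@goPerBlock, "go /",
      object@stopPerBlock, "stop )\n")
  cat("  conditions (block order):",
      paste(object@conditions[object@blockOrder], collapse = ", "), "\n")
  cat(sprintf("  HR %.1f bpm, RMSSD %.1f ms, jitter SD %g ms, noise SD %g uV\n",
              object@meanHrBpm, object@rmssdMs, object@triggerJitterSdMs,
              object@noiseSd))
})

setMethod("show", "SimulatedSession", function(object) {
  cat("SimulatedSession:", nrow(object@trials), "trials,",
      nrow(object@events), "events\n")
  if (length(object@eeg))
    cat(sprintf("  EEG: %d channels x %d samples @ %g Hz\n",
                nrow(object@eeg), ncol(object@eeg), object@config@eegFs))
  else cat("  EEG: not rendered\n")
  show(object@ecg)
})

setMethod("show", "StaircaseState", function(object) {
  cat(sprintf("StaircaseState[%s]: SSD %g ms (floor %g, cap %g, step %g)\n",
              object@condition, object@ssdMs, object@floorMs, object@maxMs,
              object@stepMs))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet[%s]: %d epochs x %d channels x %d samples, window [%g, %g) ms\n",
              object@eventType, d[1], d[2], d[3], object@windowMs[1],
              object@windowMs[2]))
  if (object@nDropped) cat("  ", object@nDropped, "events dropped (window under-run)\n")
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components x %d samples on %d channels\n",
              nrow(object@sources), ncol(object@sources),
              length(object@channels)))
  if (length(object@rankOrder)) {
    top <- object@rankOrder[seq_len(min(3L, length(object@rankOrder)))]
    cat("  top ECG-coherence:",
        paste(sprintf("%s (%.2f)", object@componentNames[top],
                      object@coherence[top]), collapse = ", "), "\n")
  }
})

setMethod("show", "AdjacencyGraph", function(object) {
  cat(sprintf("AdjacencyGraph: %d channels, %d edges (threshold %g cm)\n",
              length(object@labels), nrow(object@edges), object@thresholdCm))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cluster(s), %d significant at alpha %g (%s, %d permutations)\n",
              length(object@clusters), sum(object@significant), object@alpha,
              if (object@exhaustive) "exhaustive" else "Monte-Carlo",
              object@nPermutations))
  if (length(object@clusters)) {
    o <- order(object@pValues)
    for (i in head(o, 5)) {
      memb <- object@clusters[[i]]
      cat(sprintf("  cluster %d: %d samples, %d channels, %g-%g ms, sum t = %.1f, p = %.4g\n",
                  i, nrow(memb), length(unique(memb$channel)),
                  min(object@timesMs[memb$sample]),
                  max(object@timesMs[memb$sample]),
                  object@summedT[i], object@pValues[i]))
    }
  }
})

setMethod("show", "EffectEstimate", function(object) {
  cat("EffectEstimate:", object@formula,
      if (object@fallback) "(paired-contrast fallback)" else "", "\n")
  print(object@coefficients, digits = 4)
  cat(sprintf("  subject intercept variance: %.4g\n", object@ranefVar))
})

setMethod("show", "CfaEstimate", function(object) {
  cat(sprintf("CfaEstimate on %d channels, window [%g, %g) ms around triggers\n",
              length(object@channels), object@windowMs[1], object@windowMs[2]))
  cat("  triggers:", paste(names(object@nTriggers), object@nTriggers,
                           sep = " = ", collapse = ", "), "\n")
})
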