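# Accessor generics: user code reads slots through these, never with @.

#' @rdname CardiacTimeline-class
#' @param object a CardiacTimeline
#' @export
setGeneric("rPeakTimes", function(object) standardGeneric("rPeakTimes"))
#' @rdname CardiacTimeline-class
#' @export
setMethod("rPeakTimes", "CardiacTimeline", function(object) object@rPeakTimes)

#' @rdname CardiacTimeline-class
#' @export
setGeneric("rrIntervals", function(object) standardGeneric("rrIntervals"))
#' @rdname CardiacTimeline-class
#' @export
setMethod("rrIntervals", "CardiacTimeline", function(object) object@rrIntervals)

#' @rdname CardiacTimeline-class
#' @export
setGeneric("tEndOffsets", function(object) standardGeneric("tEndOffsets"))
#' @rdname CardiacTimeline-class
#' @export
setMethod("tEndOffsets", "CardiacTimeline", function(object) object@tEndOffsets)

#' Sampling rate of a signal-bearing object
#' @param object an EcgSignal, EpochSet or ComponentSet
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EcgSignal", function(object) object@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ComponentSet", function(object) object@fs)

#' @rdname EcgSignal-class
#' @param object an EcgSignal
#' @export
setGeneric("ecgSamples", function(object) standardGeneric("ecgSamples"))
#' @rdname EcgSignal-class
#' @export
setMethod("ecgSamples", "EcgSignal", function(object) object@samples)

#' @rdname EcgSignal-class
#' @export
setGeneric("trueRTimes", function(object) standardGeneric("trueRTimes"))
#' @rdname EcgSignal-class
#' @export
setMethod("trueRTimes", "EcgSignal", function(object)
  (object@trueRIndices - 1) / object@fs)

#' Channel labels of a multichannel object
#' @param object an EpochSet, ComponentSet or AdjacencyGraph
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EpochSet", function(object) object@channels)
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "ComponentSet", function(object) object@channels)
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "AdjacencyGraph", function(object) object@labels)

#' @rdname EpochSet-class
#' @param object an EpochSet
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)

#' @rdname EpochSet-class
#' @export
setGeneric("epochInfo", function(object) standardGeneric("epochInfo"))
#' @rdname EpochSet-class
#' @export
setMethod("epochInfo", "EpochSet", function(object) object@info)

#' @rdname EpochSet-class
#' @export
setGeneric("epochTimesMs", function(object) standardGeneric("epochTimesMs"))
#' @rdname EpochSet-class
#' @export
setMethod("epochTimesMs", "EpochSet", function(object)
  object@windowMs[1] + (seq_len(dim(object@data)[3]) - 1) * 1000 / object@fs)

#' Number of epochs/components/clusters in a container
#' @param x the container
#' @export
setMethod("length", "EpochSet", function(x) dim(x@data)[1])

#' @rdname SimulatedSession-class
#' @param object a SimulatedSession
#' @export
setGeneric("sessionEvents", function(object) standardGeneric("sessionEvents"))
#' @rdname SimulatedSession-class
#' @export
setMethod("sessionEvents", "SimulatedSession", function(object) object@events)

#' @rdname SimulatedSession-class
#' @export
setGeneric("sessionTrials", function(object) standardGeneric("sessionTrials"))
#' @rdname SimulatedSession-class
#' @export
setMethod("sessionTrials", "SimulatedSession", function(object) object@trials)

#' @rdname SimulatedSession-class
#' @export
setGeneric("sessionEeg", function(object) standardGeneric("sessionEeg"))
#' @rdname SimulatedSession-class
#' @export
setMethod("sessionEeg", "SimulatedSession", function(object) object@eeg)

#' @rdname SimulatedSession-class
#' @export
setGeneric("sessionEcg", function(object) standardGeneric("sessionEcg"))
#' @rdname SimulatedSession-class
#' @export
setMethod("sessionEcg", "SimulatedSession", function(object) object@ecg)

#' @rdname SimulatedSession-class
#' @export
setGeneric("sessionTimeline", function(object) standardGeneric("sessionTimeline"))
#' @rdname SimulatedSession-class
#' @export
setMethod("sessionTimeline", "SimulatedSession", function(object) object@timeline)

#' @rdname SimulatedSession-class
#' @export
setGeneric("sessionConfig", function(object) standardGeneric("sessionConfig"))
#' @rdname SimulatedSession-class
#' @export
setMethod("sessionConfig", "SimulatedSession", function(object) object@config)

#' @rdname SimulatedSession-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname SimulatedSession-class
#' @export
setMethod("groundTruth", "SimulatedSession", function(object) object@groundTruth)

#' @rdname StaircaseState-class
#' @param object a StaircaseState
#' @export
setGeneric("ssd", function(object) standardGeneric("ssd"))
#' @rdname StaircaseState-class
#' @export
setMethod("ssd", "StaircaseState", function(object) object@ssdMs)

#' Tabular summary of a ClusterResult
#'
#' One row per cluster: id, number of member samples, channels involved,
#' time span (ms), summed t, p-value and significance flag.
#' @param object a ClusterResult
#' @return a data.frame
#' @export
setGeneric("clusterSummary", function(object) standardGeneric("clusterSummary"))
#' @rdname clusterSummary
#' @export
setMethod("clusterSummary", "ClusterResult", function(object) {
  if (!length(object@clusters))
    return(data.frame(cluster = integer(), n_members = integer(),
                      channels = character(), t_start_ms = numeric(),
                      t_end_ms = numeric(), summed_t = numeric(),
                      p_value = numeric(), significant = logical()))
  do.call(rbind, lapply(seq_along(object@clusters), function(i) {
    memb <- object@clusters[[i]]
    data.frame(cluster = i, n_members = nrow(memb),
               channels = paste(sort(unique(object@channels[memb$channel])),
                                collapse = ","),
               t_start_ms = min(object@timesMs[memb$sample]),
               t_end_ms = max(object@timesMs[memb$sample]),
               summed_t = object@summedT[i], p_value = object@pValues[i],
               significant = object@significant[i])
  }))
})

#' @rdname ClusterResult-class
#' @param object a ClusterResult
#' @export
setGeneric("significantClusters", function(object) standardGeneric("significantClusters"))
#' @rdname ClusterResult-class
#' @export
setMethod("significantClusters", "ClusterResult", function(object)
  object@clusters[object@significant])

#' @rdname ComponentSet-class
#' @param object a ComponentSet
#' @export
setGeneric("componentCoherence", function(object) standardGeneric("componentCoherence"))
#' @rdname ComponentSet-class
#' @export
setMethod("componentCoherence", "ComponentSet", function(object) {
  z <- object@coherence
  names(z) <- object@componentNames
  z
})

#' @rdname ComponentSet-class
#' @export
setGeneric("componentRank", function(object) standardGeneric("componentRank"))
#' @rdname ComponentSet-class
#' @export
setMethod("componentRank", "ComponentSet", function(object) object@rankOrder)

#' @rdname EffectEstimate-class
#' @param object an EffectEstimate
#' @export
setGeneric("effectCoefficients", function(object) standardGeneric("effectCoefficients"))
#' @rdname EffectEstimate-class
#' @export
setMethod("effectCoefficients", "EffectEstimate", function(object) object@coefficients)
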