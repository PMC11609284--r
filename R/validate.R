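# Study-level validation experiments: end-to-end recovery of the injected
# condition effects, and false-positive calibration of the cluster test.
# These are the desk-scale analogues of the full design: fewer subjects and
# trials, a coarser EEG grid and fewer permutations, with the sensor-noise
# SD lowered so that per-subject ERP averages reach a precision comparable
# to the full design's trial counts. Injected effect sizes are always the
# generator defaults.

#' Run one scaled-down end-to-end effect-recovery experiment
#'
#' Simulates a systole vs diastole two-block experiment for several
#' subjects with the default injected condition effects (HEP, P2, N2, P3),
#' runs the full analysis chain (epoching, rejection, per-subject
#' condition averages) and the spatiotemporal cluster permutation test per
#' component family, and reports whether a significant cluster overlaps
#' the injected ROI and latency window.
#'
#' @param seed integer seed.
#' @param nSubjects simulated subjects.
#' @param trialsPerBlock,goPerBlock,stopPerBlock per-block trial counts.
#' @param eegFs EEG sampling rate (Hz).
#' @param noiseSd sensor noise SD (microvolts).
#' @param nPermutations permutations per cluster test.
#' @return named logical (hep, vep, stop, feedback): injected effect
#'   detected; NA when a family had too few usable subjects
#' @export
effectRecoveryExperiment <- function(seed, nSubjects = 8,
                                     trialsPerBlock = 52L, goPerBlock = 12L,
                                     stopPerBlock = 40L, eegFs = 125,
                                     noiseSd = 3, nPermutations = 400) {
  rois <- .roiTable()
  montage <- standardMontage()
  adj <- buildAdjacency(montage, 5)
  avg <- list()
  for (s in seq_len(nSubjects)) {
    cfg <- sessionConfigNew(conditions = c("systole", "diastole"),
                            trialsPerBlock = as.integer(trialsPerBlock),
                            goPerBlock = as.integer(goPerBlock),
                            stopPerBlock = as.integer(stopPerBlock),
                            eegFs = eegFs, noiseSd = noiseSd)
    ses <- simulateSession(cfg, seed = seed * 1000L + s)
    eeg <- sessionEeg(ses)
    for (f in names(rois)) {
      ev <- selectAnalysisEvents(ses,
        family = if (f %in% c("stop", "feedback")) f else f,
        detail = if (f == "feedback") "commission" else NULL)
      if (!nrow(ev)) next
      ep <- extractEpochs(eeg, eegFs, ev$time_s,
                          windowMs = rois[[f]]$epochMs,
                          baselineMs = c(-100, 0), eventType = f, info = ev)
      ep <- rejectEpochs(ep, 100)$epochs
      for (cc in c("systole", "diastole")) {
        ii <- which(ep@info$condition == cc)
        if (!length(ii)) next
        avg[[f]][[cc]][[paste0("s", s)]] <-
          colMeans(ep@data[ii, , , drop = FALSE], dims = 1)
      }
    }
  }
  out <- c(hep = NA, vep = NA, stop = NA, feedback = NA)
  for (f in names(rois)) {
    subj <- intersect(names(avg[[f]][["systole"]]),
                      names(avg[[f]][["diastole"]]))
    if (length(subj) < 4) next
    toArr <- function(cc) {
      ns <- dim(avg[[f]][[cc]][[subj[1]]])[2]
      a <- array(0, c(length(subj), nrow(montage), ns))
      for (i in seq_along(subj)) a[i, , ] <- avg[[f]][[cc]][[subj[i]]]
      a
    }
    A <- toArr("systole")
    B <- toArr("diastole")
    tms <- rois[[f]]$epochMs[1] + (seq_len(dim(A)[3]) - 1) * 1000 / eegFs
    res <- clusterPermutationTest(A, B, adj,
                                  nPermutations = nPermutations,
                                  seed = seed, timesMs = tms)
    hit <- FALSE
    for (k in which(res@significant)) {
      memb <- res@clusters[[k]]
      chs <- res@channels[memb$channel]
      tt <- res@timesMs[memb$sample]
      if (any(chs %in% rois[[f]]$channels &
              tt >= rois[[f]]$windowMs[1] & tt < rois[[f]]$windowMs[2]))
        hit <- TRUE
    }
    out[f] <- hit
  }
  out
}

#' Family-wise false-positive rate of the cluster test on null data
#'
#' Generates datasets in which both conditions are drawn from the same
#' standard Gaussian, runs the cluster permutation test on each, and
#' reports the fraction of datasets with any significant cluster. Channels
#' are the first \code{nChannels} electrodes of the packaged montage.
#'
#' @param nDatasets number of null datasets.
#' @param nSubjects,nChannels,nSamples dataset dimensions.
#' @param nPermutations permutations per test.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return list: \code{fpr} (fraction with any significant cluster),
#'   \code{nDatasets}, and \code{binomSe} (binomial SE at the nominal
#'   level)
#' @export
clusterTestFalsePositiveRate <- function(nDatasets = 500, nSubjects = 20,
                                         nChannels = 8, nSamples = 50,
                                         nPermutations = 1000, alpha = 0.05,
                                         seed = 1) {
  set.seed(seed)
  adj <- buildAdjacency(standardMontage()[seq_len(nChannels), ], 5)
  hits <- logical(nDatasets)
  for (i in seq_len(nDatasets)) {
    A <- array(rnorm(nSubjects * nChannels * nSamples),
               c(nSubjects, nChannels, nSamples))
    B <- array(rnorm(nSubjects * nChannels * nSamples),
               c(nSubjects, nChannels, nSamples))
    res <- clusterPermutationTest(A, B, adj, nPermutations = nPermutations,
                                  alpha = alpha)
    hits[i] <- any(res@significant)
  }
  list(fpr = mean(hits), nDatasets = nDatasets,
       binomSe = sqrt(alpha * (1 - alpha) / nDatasets))
}
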