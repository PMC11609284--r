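# Multi-stage analysis pipeline over a run directory: simulate N subjects,
# then behaviour / ECG / ERP / group statistics / report, each stage
# consuming the previous stage's on-disk outputs and recording itself in
# the run manifest. The command-line script (inst/cli/cardiostop.R) is a
# thin wrapper around runStage().

# ROI definitions: the reported component windows and electrode clusters
.roiTable <- function() {
  list(
    hep = list(channels = c("FC1", "FCz", "FC2", "C1", "Cz", "C2"),
               windowMs = c(300, 400), epochMs = c(-100, 1000)),
    vep = list(channels = c("F3", "F1", "Fz", "F2", "FC3", "FC1", "FCz",
                            "FC2", "FC4", "C3", "C1", "Cz", "C2", "C4",
                            "CPz", "CP1", "CP2"),
               windowMs = c(200, 300), epochMs = c(-100, 1000)),
    stop = list(channels = c("AFz", "F1", "Fz", "F2", "FC1", "FCz", "FC2"),
                windowMs = c(200, 300), epochMs = c(-100, 750)),
    feedback = list(channels = c("C1", "Cz", "C2", "CP1", "CPz", "CP2"),
                    windowMs = c(300, 400), epochMs = c(-100, 1000))
  )
}

.subjectDirs <- function(outDir) {
  d <- list.dirs(file.path(outDir, "sessions"), recursive = FALSE)
  if (!length(d))
    stop("stage dependency error: no simulated sessions under ", outDir,
         "; run the simulate stage first")
  sort(d)
}

.stageSimulate <- function(outDir, config, seed, nSubjects, withEeg) {
  outs <- character(0)
  for (s in seq_len(nSubjects)) {
    ses <- simulateSession(config, seed = seed + s - 1L, withEeg = withEeg)
    d <- file.path(outDir, "sessions", sprintf("subject_%02d", s))
    writeSession(ses, d)
    outs <- c(outs, d)
  }
  outs
}

.stageBehavior <- function(outDir) {
  dirs <- .subjectDirs(outDir)
  tab <- do.call(rbind, lapply(seq_along(dirs), function(s) {
    tr <- .readTsv(file.path(dirs[s], "trials.tsv"))
    cbind(subject = s, summarizeBehavior(tr))
  }))
  out <- file.path(outDir, "behavior_summary.tsv")
  .writeTsv(tab, out)
  tp <- do.call(rbind, lapply(seq_along(dirs), function(s) {
    ses <- readSession(dirs[s])
    pr <- evaluateTimingPrecision(sessionEvents(ses), sessionTimeline(ses),
                                  trials = sessionTrials(ses))
    if (!nrow(pr$summary)) return(NULL)
    cbind(subject = s, pr$summary)
  }))
  out2 <- file.path(outDir, "timing_precision.tsv")
  if (!is.null(tp)) .writeTsv(tp, out2)
  c(out, out2)
}

.stageEcg <- function(outDir) {
  dirs <- .subjectDirs(outDir)
  tab <- do.call(rbind, lapply(seq_along(dirs), function(s) {
    ses <- readSession(dirs[s])
    ecgF <- bandpassEcg(sessionEcg(ses))
    rT <- detectRPeaks(ecgF)
    ev <- sessionEvents(ses)
    rEv <- ev[ev$event_type == "r_peak", ]
    cond <- rEv$condition[findInterval(rT, rEv$time_s - 0.05)]
    cbind(subject = s, cardiacFeatures(ecgF, rT, conditions = cond))
  }))
  out <- file.path(outDir, "cardiac_features.tsv")
  .writeTsv(tab, out)
  out
}

# per-subject, per-family condition-average ERPs, stored long
.stageErp <- function(outDir, seed) {
  dirs <- .subjectDirs(outDir)
  rois <- .roiTable()
  erpRows <- list()
  roiRows <- list()
  rejRows <- list()
  for (s in seq_along(dirs)) {
    ses <- readSession(dirs[s])
    if (!length(sessionEeg(ses)))
      stop("stage dependency error: session ", dirs[s],
           " was simulated without EEG")
    cfg <- sessionConfig(ses)
    fs <- cfg@eegFs
    eeg <- preprocessEeg(sessionEeg(ses), fs)
    tl <- sessionTimeline(ses)
    cfa <- estimateCfa(eeg, fs, tl, nTriggers = 300, seed = seed + s)
    eegCfa <- subtractCfa(eeg, cfa, tl)
    for (fam in names(rois)) {
      roi <- rois[[fam]]
      evSel <- selectAnalysisEvents(ses,
        family = if (fam == "stop") "stop" else if (fam == "feedback")
          "feedback" else fam,
        detail = if (fam == "feedback") "commission" else NULL)
      if (!nrow(evSel)) next
      src <- if (fam == "vep") eegCfa else eeg   # CFA-corrected VEP trace
      ep <- extractEpochs(src, fs, evSel$time_s, windowMs = roi$epochMs,
                          baselineMs = c(-100, 0), eventType = fam,
                          info = evSel)
      rej <- rejectEpochs(ep, 100)
      rejRows[[length(rejRows) + 1L]] <-
        data.frame(subject = s, family = fam,
                   exclusion_rate = rej$exclusionRate)
      ep <- rej$epochs
      if (!length(ep)) next
      for (cc in unique(ep@info$condition)) {
        ii <- which(ep@info$condition == cc)
        sub <- initialize(ep, data = ep@data[ii, , , drop = FALSE],
                          info = ep@info[ii, , drop = FALSE])
        avg <- colMeans(sub@data, dims = 1)
        erpRows[[length(erpRows) + 1L]] <- data.frame(
          subject = s, family = fam, condition = cc,
          channel = rep(ep@channels, times = ncol(avg)),
          sample = rep(seq_len(ncol(avg)), each = nrow(avg)),
          value = as.numeric(avg))
        amp <- roiMeanAmplitude(sub, roi$channels, roi$windowMs)
        roiRows[[length(roiRows) + 1L]] <- data.frame(
          subject = s, family = fam, condition = cc, n_epochs = length(ii),
          roi_mean_uv = attr(amp, "grandMean"))
      }
    }
  }
  outs <- c(file.path(outDir, "erp_averages.tsv"),
            file.path(outDir, "roi_amplitudes.tsv"),
            file.path(outDir, "epoch_rejection.tsv"))
  .writeTsv(do.call(rbind, erpRows), outs[1])
  .writeTsv(do.call(rbind, roiRows), outs[2])
  .writeTsv(do.call(rbind, rejRows), outs[3])
  outs
}

.stageStats <- function(outDir, seed, nPermutations = 1000) {
  erpPath <- file.path(outDir, "erp_averages.tsv")
  roiPath <- file.path(outDir, "roi_amplitudes.tsv")
  if (!file.exists(erpPath) || !file.exists(roiPath))
    stop("stage dependency error: ERP outputs not found; run the erp stage first")
  erp <- .readTsv(erpPath)
  roi <- .readTsv(roiPath)
  dirs <- .subjectDirs(outDir)
  montage <- .readTsv(file.path(dirs[1], "montage.tsv"))
  adj <- buildAdjacency(montage, 5)
  rois <- .roiTable()
  fsGuess <- readSessionConfig(file.path(dirs[1], "config.yaml"))@eegFs

  clusterRows <- list()
  for (fam in unique(erp$family)) {
    sub <- erp[erp$family == fam, ]
    conds <- intersect(c("systole", "diastole"), unique(sub$condition))
    if (length(conds) < 2) next
    subjects <- sort(unique(sub$subject))
    subjects <- subjects[vapply(subjects, function(s)
      all(conds %in% sub$condition[sub$subject == s]), TRUE)]
    if (length(subjects) < 2) next
    ns <- max(sub$sample)
    toArray <- function(cc) {
      a <- array(0, c(length(subjects), length(adj@labels), ns))
      for (i in seq_along(subjects)) {
        d <- sub[sub$subject == subjects[i] & sub$condition == cc, ]
        m <- matrix(0, length(adj@labels), ns)
        m[cbind(match(d$channel, adj@labels), d$sample)] <- d$value
        a[i, , ] <- m
      }
      a
    }
    tms <- rois[[fam]]$epochMs[1] + (seq_len(ns) - 1) * 1000 / fsGuess
    res <- clusterPermutationTest(toArray("systole"), toArray("diastole"),
                                  adj, nPermutations = nPermutations,
                                  seed = seed, timesMs = tms)
    cs <- clusterSummary(res)
    if (nrow(cs)) clusterRows[[fam]] <- cbind(family = fam, cs)
  }
  outs <- file.path(outDir, c("cluster_results.tsv", "condition_effects.tsv",
                              "stats_summary.json"))
  clusterTab <- if (length(clusterRows)) do.call(rbind, clusterRows) else
    data.frame(family = character(0))
  .writeTsv(clusterTab, outs[1])

  effRows <- list()
  for (fam in unique(roi$family)) {
    d <- roi[roi$family == fam, ]
    if (length(unique(d$condition)) < 2 || length(unique(d$subject)) < 3) next
    ref <- if (fam == "vep") "systole" else
      if ("none" %in% d$condition) "none" else d$condition[1]
    est <- fitConditionEffect(d, response = "roi_mean_uv",
                              reference = ref)
    effRows[[fam]] <- cbind(family = fam, effectCoefficients(est),
                            singular = est@singular)
  }
  effTab <- if (length(effRows)) do.call(rbind, effRows) else
    data.frame(family = character(0))
  .writeTsv(effTab, outs[2])
  jsonlite::write_json(
    list(n_significant_clusters = if (nrow(clusterTab)) sum(clusterTab$significant) else 0L,
         families = unique(erp$family)),
    outs[3], auto_unbox = TRUE, pretty = TRUE)
  outs
}

.stageReport <- function(outDir) {
  if (!file.exists(file.path(outDir, "behavior_summary.tsv")))
    stop("stage dependency error: missing behavior_summary.tsv")
  report <- list(
    behavior = .readTsv(file.path(outDir, "behavior_summary.tsv")))
  for (opt in c("timing_precision", "cardiac_features", "roi_amplitudes",
                "cluster_results", "condition_effects")) {
    p <- file.path(outDir, paste0(opt, ".tsv"))
    if (file.exists(p)) report[[opt]] <- .readTsv(p)
  }
  out <- file.path(outDir, "report.json")
  jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", na = "null")
  out
}

#' Run one pipeline stage (or the whole pipeline) over a run directory
#'
#' Stages: \code{simulate} (writes one session container per subject),
#' \code{behavior} (behavioural summaries and the timing-precision audit),
#' \code{ecg} (cardiac features from the re-detected R-peaks),
#' \code{erp} (preprocessing, CFA correction, epoching, rejection,
#' per-condition averages and ROI amplitudes), \code{stats} (group
#' cluster-based permutation tests and mixed-model condition effects),
#' \code{report} (collated JSON report) and \code{all}. Consuming stages
#' fail with a stage-dependency error when their inputs are missing. Every
#' stage appends to the run manifest.
#'
#' @param stage stage name.
#' @param outDir run directory.
#' @param configPath optional YAML config (defaults otherwise).
#' @param seed integer master seed.
#' @param nSubjects simulated subjects.
#' @param nPermutations permutations for the stats stage.
#' @param withEeg render EEG during simulate.
#' @param ... config overrides passed to [readSessionConfig()].
#' @return invisibly, the paths written by the stage
#' @export
runStage <- function(stage = c("simulate", "behavior", "ecg", "erp",
                               "stats", "report", "all"),
                     outDir, configPath = NULL, seed = 1L, nSubjects = 1L,
                     nPermutations = 1000, withEeg = TRUE, ...) {
  stage <- match.arg(stage)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config <- readSessionConfig(configPath, ...)
  warns <- character(0)
  outs <- withCallingHandlers({
    switch(stage,
      simulate = .stageSimulate(outDir, config, as.integer(seed),
                                nSubjects, withEeg),
      behavior = .stageBehavior(outDir),
      ecg = .stageEcg(outDir),
      erp = .stageErp(outDir, as.integer(seed)),
      stats = .stageStats(outDir, as.integer(seed), nPermutations),
      report = .stageReport(outDir),
      all = {
        o <- c(.stageSimulate(outDir, config, as.integer(seed), nSubjects,
                              withEeg),
               .stageBehavior(outDir), .stageEcg(outDir))
        if (withEeg)
          o <- c(o, .stageErp(outDir, as.integer(seed)),
                 .stageStats(outDir, as.integer(seed), nPermutations))
        c(o, .stageReport(outDir))
      })
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  updateRunManifest(outDir, stage, as.integer(seed), configPath,
                    outputs = outs, warnings = warns)
  invisible(outs)
}
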