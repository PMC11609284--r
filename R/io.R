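# On-disk formats. A session container is a directory of plain-text files:
# tabular data as TSV (written by data.table at shortest-round-trip
# precision, so write -> read is value-exact), the configuration as YAML,
# and the signals as TSV matrices (samples x channels for EEG). A run
# manifest (JSON) records seed, config hash and per-stage inputs/outputs.

.writeTsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

.readTsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

# signals are written at %.17g so doubles survive write -> read bit-exactly
.writeSignalTsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  body <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  writeLines(do.call(paste, c(asplit(body, 2), sep = "\t")), con)
  invisible(path)
}

#' Write a simulated session to a directory container
#'
#' Writes config.yaml, events.tsv, trials.tsv, timeline.tsv, montage.tsv,
#' ground_truth_gains.tsv, ecg.tsv, eeg.tsv (when rendered) and meta.yaml.
#' Signals round-trip value-exactly. The forward-model internals (mixing,
#' sources) are not serialised; re-simulate to obtain them.
#'
#' @param session a [SimulatedSession-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSessionConfig(session@config, file.path(dir, "config.yaml"))
  .writeTsv(session@events, file.path(dir, "events.tsv"))
  .writeTsv(session@trials, file.path(dir, "trials.tsv"))
  tl <- session@timeline
  .writeTsv(data.frame(rr_ms = rrIntervals(tl)),
            file.path(dir, "timeline.tsv"))
  .writeTsv(session@montage, file.path(dir, "montage.tsv"))
  .writeTsv(groundTruth(session)$gains,
            file.path(dir, "ground_truth_gains.tsv"))
  ecg <- session@ecg
  .writeSignalTsv(matrix(ecg@samples, ncol = 1,
                         dimnames = list(NULL, "ecg_uv")),
                  file.path(dir, "ecg.tsv"))
  meta <- list(ecg_fs = ecg@fs, t0_s = rPeakTimes(tl)[1],
               true_r_indices = ecg@trueRIndices,
               seed = groundTruth(session)$seed,
               has_eeg = length(session@eeg) > 0)
  if (length(session@eeg)) {
    meta$eeg_fs <- session@config@eegFs
    .writeSignalTsv(t(session@eeg), file.path(dir, "eeg.tsv"))
  }
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a session container written by [writeSession()]
#'
#' @param dir container directory.
#' @return a [SimulatedSession-class] (without forward-model internals)
#' @export
readSession <- function(dir) {
  need <- c("config.yaml", "events.tsv", "trials.tsv", "timeline.tsv",
            "meta.yaml", "ecg.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("not a session container (missing ", paste(miss, collapse = ", "),
         "): ", dir)
  config <- readSessionConfig(file.path(dir, "config.yaml"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  tl <- cardiacTimeline(.readTsv(file.path(dir, "timeline.tsv"))$rr_ms,
                        t0 = meta$t0_s)
  ecg <- new("EcgSignal",
             samples = .readTsv(file.path(dir, "ecg.tsv"))$ecg_uv,
             fs = meta$ecg_fs,
             trueRIndices = as.integer(meta$true_r_indices))
  eeg <- matrix(numeric(0), 0, 0)
  if (isTRUE(meta$has_eeg)) {
    eegDf <- .readTsv(file.path(dir, "eeg.tsv"))
    eeg <- t(as.matrix(eegDf))
    rownames(eeg) <- names(eegDf)
  }
  gains <- .readTsv(file.path(dir, "ground_truth_gains.tsv"))
  new("SimulatedSession", config = config, timeline = tl, ecg = ecg,
      eeg = eeg, montage = .readTsv(file.path(dir, "montage.tsv")),
      events = .readTsv(file.path(dir, "events.tsv")),
      trials = .readTsv(file.path(dir, "trials.tsv")),
      groundTruth = list(templates = config@templates, gains = gains,
                         seed = meta$seed))
}

#' Append a stage record to a run manifest
#'
#' The manifest (manifest.json in the output directory) lists, per executed
#' stage: the seed, the MD5 of the config file, package version, input and
#' output paths and any warnings — enough to reproduce the run.
#'
#' @param outDir run output directory.
#' @param stage stage name.
#' @param seed integer seed used.
#' @param configPath config file the stage ran with (hashed), or NULL.
#' @param inputs,outputs character paths.
#' @param warnings character vector of warning messages.
#' @return invisibly, the manifest path
#' @export
updateRunManifest <- function(outDir, stage, seed, configPath = NULL,
                              inputs = character(0), outputs = character(0),
                              warnings = character(0)) {
  path <- file.path(outDir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list(stages = list())
  rec <- list(stage = stage, seed = seed,
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("cardiostop")),
              config_md5 = if (!is.null(configPath) && file.exists(configPath))
                unname(tools::md5sum(configPath)) else NA,
              inputs = as.list(inputs), outputs = as.list(outputs),
              warnings = as.list(warnings))
  manifest$stages[[length(manifest$stages) + 1L]] <- rec
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
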