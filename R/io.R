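## Delimited-text I/O: one CSV per trial (header row = muscle names, one
## sample per row) plus a JSON or YAML manifest mapping subjects to groups,
## trial files and MVC files.

#' Read a trial CSV into an EMGRecording
#'
#' @param path CSV file: header row of muscle names, one sample per row.
#' @param fs sampling rate in Hz.
#' @param ... metadata passed to [EMGRecording()] (subjectId, group, ...).
#' @return An [EMGRecording-class].
#' @export
readTrialCSV <- function(path, fs = 1000, ...) {
  x <- utils::read.csv(path, check.names = FALSE)
  EMGRecording(as.matrix(x), fs = fs, muscleNames = colnames(x), ...)
}

#' Write a trial or activation matrix as CSV
#'
#' [EMGRecording-class] objects are written samples x muscles with a muscle
#' header; [ActivationMatrix-class] objects are written muscles x points
#' with a muscle column.
#'
#' @param x the object to write.
#' @param path output file.
#' @export
writeTrialCSV <- function(x, path) {
  if (is(x, "EMGRecording")) {
    utils::write.csv(as.data.frame(emgSamples(x)), path, row.names = FALSE)
  } else if (is(x, "ActivationMatrix")) {
    df <- data.frame(muscle = muscleNames(x), activationValues(x),
                     check.names = FALSE)
    colnames(df)[-1] <- sprintf("pct%03d", seq_len(ncol(df) - 1) - 1)
    utils::write.csv(df, path, row.names = FALSE)
  } else stop("unsupported object type")
  invisible(path)
}

#' Read a manifest file (JSON or YAML)
#'
#' @param path manifest file; format chosen by extension (.json / .yml /
#'   .yaml).
#' @return Parsed list.
#' @export
readManifest <- function(path) {
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML manifests")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

#' Write a synthetic dataset to a directory of CSV trials
#'
#' Emits one activation CSV per trial (or raw sEMG trials plus MVC files
#' when `raw = TRUE`), a `manifest.json` describing subjects, groups and
#' files, and the generating synergy structure in `ground_truth.json`.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @param raw write raw-EMG-like traces (and per-subject MVC recordings)
#'   instead of activation matrices.
#' @param fs sampling rate for raw traces.
#' @return `dir`, invisibly.
#' @export
writeDatasetDir <- function(dataset, dir, raw = FALSE, fs = 1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- dataset@groundTruth
  man <- list(stage = if (raw) "raw" else "activation", fs = fs,
              nPoints = ncol(gt@C), muscles = gt@muscleNames,
              subjects = list())
  for (s in dataset@subjects) {
    entry <- list(id = s$subjectId, group = s$group, trials = character())
    for (i in seq_along(s$trials)) {
      f <- sprintf("%s_trial%d.csv", s$subjectId, i)
      if (raw) {
        rec <- synthesizeRawEMG(s$trials[[i]], fs = fs,
                                seed = dataset@seed + 7919L * i,
                                subjectId = s$subjectId, group = s$group,
                                trialIndex = i)
        writeTrialCSV(rec, file.path(dir, f))
      } else {
        writeTrialCSV(s$trials[[i]], file.path(dir, f))
      }
      entry$trials <- c(entry$trials, f)
    }
    if (raw) {
      fm <- sprintf("%s_mvc.csv", s$subjectId)
      writeTrialCSV(synthesizeMVCRecording(gt@muscleNames, fs = fs,
                                           seed = dataset@seed + 13L,
                                           subjectId = s$subjectId),
                    file.path(dir, fm))
      entry$mvc <- fm
    }
    man$subjects[[length(man$subjects) + 1L]] <- entry
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(W = gt@W, C = gt@C, muscles = gt@muscleNames,
                            snrDb = dataset@snrDb, seed = dataset@seed),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [writeDatasetDir()]
#'
#' @param dir directory containing `manifest.json` and trial CSVs.
#' @return list with `stage` (`"raw"` or `"activation"`), `fs`, and
#'   `subjects`: per subject id, group, trial objects ([EMGRecording-class]
#'   or [ActivationMatrix-class]) and, for raw data, the MVC recording.
#' @export
readDatasetDir <- function(dir) {
  man <- readManifest(file.path(dir, "manifest.json"))
  subjects <- lapply(man$subjects, function(entry) {
    trials <- lapply(seq_along(entry$trials), function(i) {
      f <- file.path(dir, entry$trials[[i]])
      if (man$stage == "raw") {
        readTrialCSV(f, fs = man$fs, subjectId = entry$id,
                     group = entry$group, trialIndex = i)
      } else {
        df <- utils::read.csv(f, check.names = FALSE)
        ActivationMatrix(as.matrix(df[, -1]), muscleNames = df$muscle,
                         subjectId = entry$id, group = entry$group,
                         trialIndex = i)
      }
    })
    out <- list(subjectId = entry$id, group = entry$group, trials = trials)
    if (!is.null(entry$mvc))
      out$mvc <- readTrialCSV(file.path(dir, entry$mvc), fs = man$fs,
                              subjectId = entry$id, group = entry$group)
    out
  })
  list(stage = man$stage, fs = man$fs, subjects = subjects)
}
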