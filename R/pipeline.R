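## End-to-end orchestration: (raw EMG ->) activation matrices -> per-subject
## NNMF with dual-VAF rank selection -> reference synergies from the healthy
## group -> Pearson classification -> weight and coefficient statistics.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the study defaults: 50 Hz
#' notch / 30 Hz high-pass / 5 Hz low-pass envelope filters, 10 ms
#' electromechanical delay, shape factor 1.5, dual-VAF thresholds 90% / 75%,
#' silhouette search over 2..8 clusters, Pearson threshold r > 0.6,
#' alpha = 0.05 and 101 phase points.
#'
#' @param notchHz,highpassHz,lowpassHz,notchQ,filterOrder envelope filters.
#' @param C1,C2,dMs,An activation-model parameters ([activationParams()]).
#' @param clipMvc cap normalized EMG at 1 before the activation model.
#' @param nPoints phase points per trial.
#' @param kMax,vafGlobalMin,vafLocalMin,nRestarts,maxIter,tol rank selection.
#' @param iRange,nInit reference-synergy clustering.
#' @param rMin Pearson classification threshold.
#' @param alpha significance level for all tests.
#' @param nPerm SPM permutations.
#' @param referenceGroup group whose synergies build the reference set
#'   (default `"healthy"`); `"both"` pools the two groups.
#' @param seed master seed for every stochastic stage.
#' @return Named list of settings, class `"SynergyPipelineConfig"`.
#' @export
synergyConfig <- function(notchHz = 50, highpassHz = 30, lowpassHz = 5,
                          notchQ = 30, filterOrder = 4,
                          C1 = -0.5, C2 = -0.5, dMs = 10, An = 1.5,
                          clipMvc = TRUE, nPoints = 101,
                          kMax = 8, vafGlobalMin = 0.90, vafLocalMin = 0.75,
                          nRestarts = 20, maxIter = 1000, tol = 1e-6,
                          iRange = 2:8, nInit = 50, rMin = 0.6,
                          alpha = 0.05, nPerm = 10000,
                          referenceGroup = "healthy", seed = 1L) {
  cfg <- list(notchHz = notchHz, highpassHz = highpassHz,
              lowpassHz = lowpassHz, notchQ = notchQ,
              filterOrder = filterOrder, C1 = C1, C2 = C2, dMs = dMs,
              An = An, clipMvc = clipMvc, nPoints = nPoints, kMax = kMax,
              vafGlobalMin = vafGlobalMin, vafLocalMin = vafLocalMin,
              nRestarts = nRestarts, maxIter = maxIter, tol = tol,
              iRange = iRange, nInit = nInit, rMin = rMin, alpha = alpha,
              nPerm = nPerm, referenceGroup = referenceGroup,
              seed = as.integer(seed))
  stopifnot(cfg$nPoints >= 2, cfg$kMax >= 1,
            cfg$vafGlobalMin > 0, cfg$vafGlobalMin <= 1,
            cfg$vafLocalMin > 0, cfg$vafLocalMin <= 1,
            cfg$rMin >= -1, cfg$rMin <= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$referenceGroup %in% c("healthy", "CAI", "both"))
  # validates the activation block
  activationParams(cfg$C1, cfg$C2, cfg$dMs, cfg$An)
  structure(cfg, class = "SynergyPipelineConfig")
}

.subjectActivation <- function(subject, cfg, fs) {
  # raw path: preprocess + MVC-normalize + activation model per trial
  if (is(subject$trials[[1]], "ActivationMatrix")) return(subject$trials)
  ref <- computeMVCPeak(subject$mvc, notchHz = cfg$notchHz,
                        highpassHz = cfg$highpassHz,
                        lowpassHz = cfg$lowpassHz, notchQ = cfg$notchQ,
                        order = cfg$filterOrder)
  params <- activationParams(cfg$C1, cfg$C2, cfg$dMs, cfg$An)
  lapply(subject$trials, function(tr) {
    env <- preprocessEMG(tr, notchHz = cfg$notchHz,
                         highpassHz = cfg$highpassHz,
                         lowpassHz = cfg$lowpassHz, notchQ = cfg$notchQ,
                         order = cfg$filterOrder)
    activationFromEMG(mvcNormalize(env, ref, clip = cfg$clipMvc),
                      params, nPoints = cfg$nPoints)
  })
}

#' Concatenate a subject's trials into one activation data matrix
#'
#' @param trials list of [ActivationMatrix-class] (same muscles, same
#'   point count).
#' @return muscles x (nPoints * nTrials) matrix.
#' @export
assembleDataMatrix <- function(trials) {
  do.call(cbind, lapply(trials, activationValues))
}

#' Run the full synergy pipeline
#'
#' Stages: (1) activation matrices per trial (from raw sEMG via envelope
#' preprocessing, MVC normalization and the activation model when the input
#' is raw; synthetic activation trials pass through); (2) per-subject NNMF
#' with dual-VAF rank selection on the trial-concatenated matrix;
#' (3) reference synergies by silhouette-optimal K-means over the reference
#' group's pooled synergy vectors; (4) Pearson classification of every
#' subject synergy and per-group similarity rates; (5) group statistics:
#' routed tests + Cohen's d per (reference synergy, muscle) and permutation
#' SPM on activation-coefficient curves.
#'
#' @param input a [SyntheticDataset-class], a dataset directory (see
#'   [writeDatasetDir()]), or a list of subject entries (each with
#'   `subjectId`, `group`, `trials`, optionally `mvc`).
#' @param config a [synergyConfig()] object.
#' @param outDir optional directory; when given, stage outputs are written
#'   as CSV/JSON reports.
#' @return list with elements `perSubject` (data.frame of selected synergy
#'   numbers and VAFs), `decompositions`, `reference`
#'   ([ReferenceSynergySet-class]), `matches` (per group
#'   [SynergyMatch-class]), `similarity` (per-group % classified),
#'   `weightComparison` (data.frame), `spm` (per-reference SPM results) and
#'   `config`.
#' @export
runPipeline <- function(input, config = synergyConfig(), outDir = NULL) {
  cfg <- config
  if (is.character(input) && length(input) == 1L) {
    ds <- readDatasetDir(input)
    subjects <- ds$subjects
    fs <- ds$fs
  } else if (is(input, "SyntheticDataset")) {
    subjects <- input@subjects
    fs <- 1000
  } else {
    subjects <- input
    fs <- 1000
  }
  if (!length(subjects)) stop("pipeline stage 'input': no subjects found")

  # stage 1+2: activation matrices and per-subject rank selection
  decomps <- list()
  perSubject <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    sel <- tryCatch({
      trials <- .subjectActivation(s, cfg, fs)
      V <- assembleDataMatrix(trials)
      selectSynergyNumber(V, kMax = cfg$kMax,
                          vafGlobalMin = cfg$vafGlobalMin,
                          vafLocalMin = cfg$vafLocalMin,
                          seed = cfg$seed + i, nRestarts = cfg$nRestarts,
                          maxIter = cfg$maxIter, tol = cfg$tol,
                          subjectId = s$subjectId, group = s$group)
    }, error = function(e) {
      stop(sprintf("pipeline stage 'decomposition', subject %s: %s",
                   s$subjectId, conditionMessage(e)), call. = FALSE)
    })
    d <- sel@decompositions[[sel@nopt]]
    decomps[[i]] <- d
    perSubject[[i]] <- data.frame(
      subject = s$subjectId, group = s$group, nopt = sel@nopt,
      thresholdsMet = sel@thresholdsMet, vafGlobal = d@vafGlobal,
      minVafLocal = min(d@vafLocal, na.rm = TRUE))
  }
  perSubject <- do.call(rbind, perSubject)

  # stage 3: reference synergies from the reference group
  groups <- perSubject$group
  refIdx <- if (cfg$referenceGroup == "both") seq_along(decomps)
            else which(groups == cfg$referenceGroup)
  if (!length(refIdx))
    stop("pipeline stage 'reference': no subjects in reference group")
  refPool <- buildSynergyPool(decomps[refIdx], nPoints = cfg$nPoints)
  reference <- selectClusterNumber(refPool@D, kRange = cfg$iRange,
                                   seed = cfg$seed, nInit = cfg$nInit)

  # stage 4: classification per group
  matches <- list()
  for (g in sort(unique(groups))) {
    pool <- buildSynergyPool(decomps[groups == g], nPoints = cfg$nPoints)
    matches[[g]] <- matchToReference(pool, reference, rMin = cfg$rMin)
  }
  simRates <- vapply(matches,
                     function(m) unname(similarityRate(m)[1]), numeric(1))

  # stage 5: group statistics (only with two groups present)
  weightComparison <- NULL
  spm <- NULL
  if (length(matches) == 2L) {
    weightComparison <- suppressWarnings(
      compareGroupWeights(matches[[1]], matches[[2]], alpha = cfg$alpha))
    spm <- compareGroupCoefficients(matches[[1]], matches[[2]],
                                    alpha = cfg$alpha, nPerm = cfg$nPerm,
                                    seed = cfg$seed)
  }

  result <- list(perSubject = perSubject, decompositions = decomps,
                 reference = reference, matches = matches,
                 similarity = simRates, weightComparison = weightComparison,
                 spm = spm, config = cfg)
  if (!is.null(outDir)) .writePipelineReports(result, outDir)
  result
}

.writePipelineReports <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$perSubject,
                   file.path(outDir, "rank_selection.csv"), row.names = FALSE)
  ref <- result$reference
  utils::write.csv(data.frame(muscle = ref@muscleNames,
                              referenceCentroids(ref), check.names = FALSE),
                   file.path(outDir, "reference_synergies.csv"),
                   row.names = FALSE)
  utils::write.csv(ref@silhouetteTable,
                   file.path(outDir, "silhouette.csv"), row.names = FALSE)
  matchTab <- do.call(rbind, lapply(result$matches, matchTable))
  utils::write.csv(matchTab, file.path(outDir, "match_report.csv"),
                   row.names = FALSE)
  if (!is.null(result$weightComparison))
    utils::write.csv(result$weightComparison,
                     file.path(outDir, "weight_comparison.csv"),
                     row.names = FALSE)
  summary <- list(
    nSubjects = nrow(result$perSubject),
    noptBySubject = stats::setNames(result$perSubject$nopt,
                                    result$perSubject$subject),
    nReferenceSynergies = ref@chosenK,
    silhouette = ref@silhouetteMean,
    similarity = as.list(result$similarity),
    thresholdsMetAll = all(result$perSubject$thresholdsMet))
  if (!is.null(result$spm))
    summary$spm <- lapply(result$spm, function(s)
      list(threshold = s$threshold, clusters = s$clusters))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(outDir)
}
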