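#' @import methods
NULL

#' Default muscle montage
#'
#' Ordered labels of the ten lower-limb muscles recorded during single-leg
#' landing: soleus (SL), medial/lateral gastrocnemius (MG, LG), tibialis
#' anterior (TA), peroneus longus (PL), rectus femoris (RF), vastus
#' medialis/lateralis (VM, VL), biceps femoris (BF) and gluteus maximus (GM).
#'
#' @return Character vector of length 10.
#' @export
defaultMuscles <- function() {
  c("SL", "MG", "LG", "TA", "PL", "RF", "VM", "VL", "BF", "GM")
}

.STAGES <- c("raw", "envelope", "normalized")
.GROUPS <- c("CAI", "healthy")

#' EMGRecording: one multi-channel sEMG trial
#'
#' Container for a single trial of multi-channel surface EMG, at any of the
#' three processing stages: `raw` (as recorded), `envelope` (notch,
#' high-pass, rectification, low-pass applied) or `normalized` (envelope
#' divided by the per-muscle MVC peak).
#'
#' @slot samples numeric matrix, one row per sample, one column per muscle.
#' @slot fs sampling rate in Hz.
#' @slot muscleNames ordered channel labels (see [defaultMuscles()]).
#' @slot subjectId subject identifier.
#' @slot group group label, `"CAI"` or `"healthy"` (may be `NA`).
#' @slot trialIndex integer trial number within subject.
#' @slot stage processing stage, one of `"raw"`, `"envelope"`, `"normalized"`.
#'
#' @seealso [EMGRecording()], [preprocessEMG()], [mvcNormalize()]
#' @export
setClass("EMGRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    muscleNames = "character",
    subjectId = "character",
    group = "character",
    trialIndex = "integer",
    stage = "character"
  )
)

setValidity("EMGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (ncol(object@samples) != length(object@muscleNames))
    msg <- c(msg, "ncol(samples) must equal length(muscleNames)")
  if (anyDuplicated(object@muscleNames))
    msg <- c(msg, "muscleNames must be unique")
  if (!(object@stage %in% .STAGES))
    msg <- c(msg, sprintf("stage must be one of: %s", paste(.STAGES, collapse = ", ")))
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite (no NA/NaN/Inf)")
  if (object@stage == "envelope" && nrow(object@samples) && min(object@samples) < 0)
    msg <- c(msg, "envelope-stage samples must be non-negative")
  # normalized EMG can exceed 1 when task EMG exceeds the MVC peak and
  # clipping is disabled; only non-negativity is structural
  if (object@stage == "normalized" && nrow(object@samples) &&
      min(object@samples) < 0)
    msg <- c(msg, "normalized-stage samples must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an EMGRecording
#'
#' @param samples numeric matrix (samples x muscles) or data.frame.
#' @param fs sampling rate in Hz (default 1000).
#' @param muscleNames channel labels; defaults to `colnames(samples)` or
#'   [defaultMuscles()] when the column count is 10.
#' @param subjectId,group,trialIndex trial metadata.
#' @param stage processing stage flag.
#' @return An [EMGRecording-class] object.
#' @examples
#' x <- matrix(rnorm(1000 * 10), 1000, 10)
#' rec <- EMGRecording(x, fs = 1000)
#' @export
EMGRecording <- function(samples, fs = 1000, muscleNames = NULL,
                         subjectId = NA_character_, group = NA_character_,
                         trialIndex = 1L, stage = "raw") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(muscleNames)) {
    muscleNames <- colnames(samples)
    if (is.null(muscleNames)) {
      muscleNames <- if (ncol(samples) == 10L) defaultMuscles()
                     else paste0("M", seq_len(ncol(samples)))
    }
  }
  colnames(samples) <- muscleNames
  new("EMGRecording", samples = samples, fs = as.numeric(fs),
      muscleNames = as.character(muscleNames),
      subjectId = as.character(subjectId), group = as.character(group),
      trialIndex = as.integer(trialIndex), stage = stage)
}

#' MVCReference: per-muscle maximal-contraction peaks
#'
#' Peak of the processed MVC envelope for every muscle; defines 100%
#' activation for MVC normalization.
#'
#' @slot peaks named numeric vector of positive peak values.
#' @slot source free-text provenance (e.g. originating trial id).
#' @export
setClass("MVCReference",
  representation(peaks = "numeric", source = "character"))

setValidity("MVCReference", function(object) {
  if (is.null(names(object@peaks)) || anyDuplicated(names(object@peaks)))
    return("peaks must be uniquely named by muscle")
  if (any(!is.finite(object@peaks)) || any(object@peaks <= 0))
    return("every MVC peak must be finite and > 0")
  TRUE
})

#' @rdname MVCReference-class
#' @param peaks named numeric vector of per-muscle peaks.
#' @param source provenance string.
#' @export
MVCReference <- function(peaks, source = NA_character_) {
  new("MVCReference", peaks = peaks, source = as.character(source))
}

#' ActivationMatrix: time-normalized muscle activations for one trial
#'
#' Muscle activation a_n(t) in `[0, 1]`, one row per muscle, time-normalized
#' to the landing phase (101 points = 0-100% by default).
#'
#' @slot values numeric matrix (muscles x points), entries in `[0, 1]`.
#' @slot muscleNames ordered row labels.
#' @slot subjectId,group,trialIndex trial metadata.
#' @export
setClass("ActivationMatrix",
  representation(
    values = "matrix",
    muscleNames = "character",
    subjectId = "character",
    group = "character",
    trialIndex = "integer"
  )
)

setValidity("ActivationMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@muscleNames))
    msg <- c(msg, "nrow(values) must equal length(muscleNames)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  else if (length(object@values) &&
           (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-9))
    msg <- c(msg, "activation values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname ActivationMatrix-class
#' @param values muscles x points matrix in `[0, 1]`.
#' @param muscleNames row labels; defaults to rownames.
#' @param subjectId,group,trialIndex metadata.
#' @export
ActivationMatrix <- function(values, muscleNames = NULL,
                             subjectId = NA_character_, group = NA_character_,
                             trialIndex = 1L) {
  values <- as.matrix(values)
  if (is.null(muscleNames)) {
    muscleNames <- rownames(values)
    if (is.null(muscleNames)) {
      muscleNames <- if (nrow(values) == 10L) defaultMuscles()
                     else paste0("M", seq_len(nrow(values)))
    }
  }
  rownames(values) <- muscleNames
  new("ActivationMatrix", values = pmin(pmax(values, 0), 1),
      muscleNames = as.character(muscleNames),
      subjectId = as.character(subjectId), group = as.character(group),
      trialIndex = as.integer(trialIndex))
}

#' SynergyDecomposition: one NNMF factorization V ~ W C
#'
#' Result of a non-negative matrix factorization of an activation matrix
#' into `k` synergy vectors (columns of `W`, unit Euclidean norm) and
#' activation coefficients (rows of `C`).
#'
#' @slot W muscles x k non-negative matrix; columns have unit 2-norm.
#' @slot C k x n_total non-negative coefficient matrix.
#' @slot k number of synergies.
#' @slot vafGlobal global variance accounted for (fraction).
#' @slot vafLocal per-muscle VAF vector.
#' @slot lossTrace Frobenius loss at each multiplicative-update iteration
#'   of the winning restart.
#' @slot seed,nRestarts restart metadata.
#' @slot converged whether the relative-loss tolerance was met.
#' @slot subjectId,group provenance.
#' @export
setClass("SynergyDecomposition",
  representation(
    W = "matrix", C = "matrix", k = "integer",
    vafGlobal = "numeric", vafLocal = "numeric",
    lossTrace = "numeric", seed = "integer", nRestarts = "integer",
    converged = "logical", subjectId = "character", group = "character"
  )
)

setValidity("SynergyDecomposition", function(object) {
  msg <- character()
  if (min(object@W) < 0 || min(object@C) < 0)
    msg <- c(msg, "W and C must be non-negative")
  if (ncol(object@W) != object@k || nrow(object@C) != object@k)
    msg <- c(msg, "inner dimensions must equal k")
  nrm <- sqrt(colSums(object@W^2))
  if (any(abs(nrm[nrm > 0] - 1) > 1e-9))
    msg <- c(msg, "non-null columns of W must have unit Euclidean norm")
  if (length(object@vafGlobal) && object@vafGlobal > 1 + 1e-12)
    msg <- c(msg, "vafGlobal cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' SynergyRankSelection: dual-VAF choice of the synergy number
#'
#' Per-k decompositions plus the smallest k whose global VAF and every
#' per-muscle VAF meet their thresholds.
#'
#' @slot nopt selected synergy number.
#' @slot thresholdsMet FALSE when no k in 1..kMax met both thresholds
#'   (then `nopt == kMax`).
#' @slot vafTable data.frame with columns k, vafGlobal, minVafLocal.
#' @slot decompositions list of [SynergyDecomposition-class], one per k.
#' @slot vafGlobalMin,vafLocalMin thresholds used.
#' @export
setClass("SynergyRankSelection",
  representation(
    nopt = "integer", thresholdsMet = "logical", vafTable = "data.frame",
    decompositions = "list", vafGlobalMin = "numeric", vafLocalMin = "numeric"
  )
)

#' SynergyPool: stacked synergy vectors from many subjects
#'
#' @slot D muscles x k_total matrix of unit-norm synergy-vector columns.
#' @slot provenance data.frame (one row per column of D) with subject,
#'   group and within-subject synergy index.
#' @slot coefficients k_total x nPoints matrix; each row is the trial-averaged
#'   activation-coefficient curve attached to the corresponding column of D.
#' @slot muscleNames row labels of D.
#' @export
setClass("SynergyPool",
  representation(D = "matrix", provenance = "data.frame",
                 coefficients = "matrix", muscleNames = "character"))

setValidity("SynergyPool", function(object) {
  msg <- character()
  if (ncol(object@D) != nrow(object@provenance))
    msg <- c(msg, "one provenance row per column of D required")
  if (nrow(object@coefficients) && nrow(object@coefficients) != ncol(object@D))
    msg <- c(msg, "one coefficient row per column of D required")
  if (length(msg)) msg else TRUE
})

#' ReferenceSynergySet: K-means reference synergies
#'
#' Cluster centroids of pooled synergy vectors, used as the baseline
#' reference against which every subject's synergies are classified.
#'
#' @slot centroids muscles x i matrix of cluster centroids.
#' @slot assignment integer cluster id per pooled synergy vector.
#' @slot distortion final K-means distortion J.
#' @slot silhouetteMean mean silhouette at the chosen i.
#' @slot silhouetteTable data.frame (i, silhouette) over the searched range.
#' @slot chosenK selected cluster count.
#' @slot muscleNames row labels.
#' @export
setClass("ReferenceSynergySet",
  representation(
    centroids = "matrix", assignment = "integer", distortion = "numeric",
    silhouetteMean = "numeric", silhouetteTable = "data.frame",
    chosenK = "integer", muscleNames = "character"
  )
)

setValidity("ReferenceSynergySet", function(object) {
  msg <- character()
  if (object@distortion < 0) msg <- c(msg, "distortion must be >= 0")
  if (length(object@silhouetteMean) &&
      (object@silhouetteMean < -1 - 1e-12 || object@silhouetteMean > 1 + 1e-12))
    msg <- c(msg, "silhouette must lie in [-1, 1]")
  if (ncol(object@centroids) != object@chosenK)
    msg <- c(msg, "ncol(centroids) must equal chosenK")
  if (length(msg)) msg else TRUE
})

#' SynergyMatch: Pearson classification of pooled synergies
#'
#' Each pooled synergy vector is matched to the reference centroid with the
#' highest Pearson correlation and classified when r exceeds the threshold;
#' its activation-coefficient curve inherits the assignment.
#'
#' @slot table data.frame: subject, group, synergyIndex, bestRef, r, classified.
#' @slot rMatrix k_total x i matrix of correlations against every centroid.
#' @slot pool the matched [SynergyPool-class].
#' @slot rMin classification threshold.
#' @export
setClass("SynergyMatch",
  representation(table = "data.frame", rMatrix = "matrix",
                 pool = "SynergyPool", rMin = "numeric"))

#' GroundTruth: generating synergy structure for synthetic data
#'
#' @slot W muscles x kTrue unit-norm template synergy vectors (healthy-like).
#' @slot groupTemplates named list of per-group template matrices (columns
#'   renormalized after group-specific weight shifts).
#' @slot weightSd named list of per-group muscles x kTrue matrices of
#'   between-subject weight standard deviations.
#' @slot C kTrue x nPoints non-negative activation-coefficient profiles.
#' @slot muscleNames row labels.
#' @slot snrDb default signal-to-noise ratio in dB.
#' @slot seed generator seed.
#' @export
setClass("GroundTruth",
  representation(
    W = "matrix", groupTemplates = "list", weightSd = "list",
    C = "matrix", muscleNames = "character", snrDb = "numeric",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (min(object@W) < 0 || min(object@C) < 0)
    msg <- c(msg, "W and C must be non-negative")
  if (ncol(object@W) > nrow(object@W))
    msg <- c(msg, "kTrue must not exceed the muscle count")
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: simulated landing study
#'
#' @slot subjects list; each element holds subjectId, group, the subject's
#'   generating synergy vectors (`Wtrue`), and a list of trial
#'   [ActivationMatrix-class] objects.
#' @slot groundTruth the [GroundTruth-class] used.
#' @slot seed master seed.
#' @slot snrDb noise level used.
#' @export
setClass("SyntheticDataset",
  representation(subjects = "list", groundTruth = "GroundTruth",
                 seed = "integer", snrDb = "numeric"))

## ---- show methods -------------------------------------------------------

setMethod("show", "EMGRecording", function(object) {
  cat(sprintf("EMGRecording [%s]: %d samples x %d muscles @ %g Hz\n",
              object@stage, nrow(object@samples), ncol(object@samples),
              object@fs))
  cat(sprintf("  subject=%s group=%s trial=%d\n",
              object@subjectId, object@group, object@trialIndex))
})

setMethod("show", "ActivationMatrix", function(object) {
  cat(sprintf("ActivationMatrix: %d muscles x %d points (subject=%s, group=%s)\n",
              nrow(object@values), ncol(object@values),
              object@subjectId, object@group))
})

setMethod("show", "SynergyDecomposition", function(object) {
  cat(sprintf("SynergyDecomposition: k=%d, global VAF=%.4f, min local VAF=%.4f\n",
              object@k, object@vafGlobal, min(object@vafLocal)))
})

setMethod("show", "SynergyRankSelection", function(object) {
  cat(sprintf("SynergyRankSelection: nopt=%d (thresholds %s)\n",
              object@nopt,
              if (object@thresholdsMet) "met" else "NOT met"))
  print(object@vafTable, row.names = FALSE)
})

setMethod("show", "ReferenceSynergySet", function(object) {
  cat(sprintf("ReferenceSynergySet: %d reference synergies, mean silhouette %.3f\n",
              object@chosenK, object@silhouetteMean))
})

setMethod("show", "SynergyMatch", function(object) {
  cl <- object@table$classified
  cat(sprintf("SynergyMatch: %d/%d synergies classified (r > %.2f)\n",
              sum(cl), length(cl), object@rMin))
})

setMethod("show", "SyntheticDataset", function(object) {
  grp <- vapply(object@subjects, function(s) s$group, character(1))
  cat(sprintf("SyntheticDataset: %d subjects (%s), %d true modules, SNR %g dB\n",
              length(object@subjects),
              paste(sprintf("%s=%d", names(table(grp)), table(grp)),
                    collapse = ", "),
              ncol(object@groundTruth@W), object@snrDb))
})
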