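## Synthetic landing data with known synergy structure. Group-specific
## synergy-vector templates and between-subject weight variability follow
## the published group means and SDs for the four landing modules (hip,
## knee, ankle-initial-contact, whole-limb); activation-coefficient
## profiles are Gaussian bumps at the reported module timings.

# per-muscle template means and between-subject SDs for the four modules,
# rows ordered as defaultMuscles(): SL MG LG TA PL RF VM VL BF GM
.SYN_MEAN <- list(
  healthy = matrix(c(
    # S1    S2    S3    S4
    0.09, 0.44, 0.11, 0.58,   # SL
    0.25, 0.43, 0.74, 0.19,   # MG
    0.23, 0.43, 0.41, 0.52,   # LG
    0.26, 0.13, 0.48, 0.04,   # TA
    0.11, 0.14, 0.24, 0.53,   # PL
    0.07, 0.92, 0.13, 0.52,   # RF
    0.12, 0.43, 0.12, 0.64,   # VM
    0.22, 0.46, 0.12, 0.31,   # VL
    0.68, 0.04, 0.13, 0.22,   # BF
    0.32, 0.02, 0.11, 0.43),  # GM
    nrow = 10, byrow = TRUE),
  CAI = matrix(c(
    0.10, 0.40, 0.20, 0.54,
    0.27, 0.41, 0.69, 0.18,
    0.25, 0.30, 0.47, 0.30,
    0.25, 0.09, 0.64, 0.08,
    0.13, 0.29, 0.21, 0.31,
    0.11, 0.90, 0.10, 0.49,
    0.11, 0.39, 0.16, 0.54,
    0.24, 0.30, 0.13, 0.45,
    0.71, 0.03, 0.28, 0.08,
    0.50, 0.13, 0.16, 0.37),
    nrow = 10, byrow = TRUE)
)

.SYN_SD <- list(
  healthy = matrix(c(
    0.05, 0.18, 0.07, 0.16,
    0.15, 0.26, 0.27, 0.15,
    0.12, 0.21, 0.23, 0.20,
    0.12, 0.10, 0.22, 0.06,
    0.09, 0.12, 0.23, 0.30,
    0.10, 0.17, 0.12, 0.35,
    0.11, 0.23, 0.11, 0.21,
    0.14, 0.20, 0.11, 0.15,
    0.15, 0.05, 0.11, 0.15,
    0.13, 0.03, 0.07, 0.19),
    nrow = 10, byrow = TRUE),
  CAI = matrix(c(
    0.10, 0.26, 0.15, 0.14,
    0.18, 0.18, 0.31, 0.17,
    0.19, 0.18, 0.20, 0.14,
    0.16, 0.08, 0.31, 0.07,
    0.10, 0.20, 0.14, 0.20,
    0.11, 0.13, 0.10, 0.22,
    0.10, 0.22, 0.13, 0.28,
    0.20, 0.20, 0.09, 0.17,
    0.14, 0.07, 0.20, 0.07,
    0.25, 0.18, 0.11, 0.29),
    nrow = 10, byrow = TRUE)
)

# activation-profile timing: module centres and widths in % of landing phase
# (ankle module confined to initial contact; hip and knee bursts mid-phase;
# the whole-limb module late, toward stabilization)
.C_CENTER <- c(25, 50, 8, 78)
.C_WIDTH  <- c(8, 14, 5, 9)
.C_GAIN   <- c(0.79, 1, 0.67, 0.95)

# group-mean weights are blurred by averaging across subjects; the
# generating templates restore subject-level contrast by squaring the
# printed means before renormalization
.W_SHARPEN <- 3

.unitCols <- function(W) {
  nrm <- sqrt(colSums(W^2))
  sweep(W, 2, ifelse(nrm > 0, nrm, 1), "/")
}

#' Ground-truth synergy structure
#'
#' Builds the generating structure for synthetic landing trials: unit-norm
#' module templates for a CAI-like and a healthy-like group (derived from
#' group-mean weights of the four landing modules), per-cell between-subject
#' weight SDs, and non-negative Gaussian-bump activation-coefficient
#' profiles whose amplitudes are scaled so all modules contribute comparable
#' signal energy.
#'
#' @param m number of muscles; only the default 10-muscle montage carries
#'   the module templates, other values get random-block templates.
#' @param kTrue number of generating modules (default 4; must be <= m and,
#'   for the template path, <= 4).
#' @param nPoints phase points per trial (default 101).
#' @param seed RNG seed (used only for the non-default random-template path).
#' @param snrDb default signal-to-noise ratio in dB attached to the object.
#' @param weightSdScale fraction of the tabulated between-subject weight SDs
#'   attributed to true subject-level variability (default 0.5). The
#'   remainder of the observed spread arises in simulation from trial noise
#'   and factorization estimation error, which the pipeline adds itself.
#' @return A [GroundTruth-class].
#' @examples
#' gt <- makeGroundTruth()
#' dim(gt@W)  # 10 x 4
#' @export
makeGroundTruth <- function(m = 10, kTrue = 4, nPoints = 101, seed = 1L,
                            snrDb = 20, weightSdScale = 0.5) {
  if (kTrue > m) stop("kTrue cannot exceed the muscle count")
  if (m == 10 && kTrue <= 4) {
    muscles <- defaultMuscles()
    tmplH <- .SYN_MEAN$healthy[, seq_len(kTrue), drop = FALSE]^.W_SHARPEN
    tmplC <- .SYN_MEAN$CAI[, seq_len(kTrue), drop = FALSE]^.W_SHARPEN
    sdH <- weightSdScale * .SYN_SD$healthy[, seq_len(kTrue), drop = FALSE]
    sdC <- weightSdScale * .SYN_SD$CAI[, seq_len(kTrue), drop = FALSE]
    centers <- .C_CENTER[seq_len(kTrue)]
    widths <- .C_WIDTH[seq_len(kTrue)]
    gains <- .C_GAIN[seq_len(kTrue)]
  } else {
    # random block templates: each module dominated by a distinct muscle set
    muscles <- paste0("M", seq_len(m))
    set.seed(seed)
    tmplH <- matrix(runif(m * kTrue, 0, 0.15), m, kTrue)
    blocks <- split(seq_len(m), rep(seq_len(kTrue), length.out = m))
    for (j in seq_len(kTrue))
      tmplH[blocks[[j]], j] <- runif(length(blocks[[j]]), 0.6, 1)
    tmplC <- tmplH
    sdH <- sdC <- matrix(0.12, m, kTrue)
    centers <- seq(10, 80, length.out = kTrue)
    widths <- rep(12, kTrue)
    gains <- rep(1, kTrue)
  }
  rownames(tmplH) <- rownames(tmplC) <- muscles
  pct <- seq(0, 100, length.out = nPoints)
  C <- t(vapply(seq_len(kTrue),
                function(j) exp(-0.5 * ((pct - centers[j]) / widths[j])^2),
                numeric(nPoints)))
  # balance module energies via the gains, then scale the loudest entry of
  # the noiseless reconstruction W C to ~0.85 (activation headroom)
  W <- .unitCols(tmplH)
  C <- sweep(C, 1, gains / sqrt(rowSums(C^2)), "*")
  C <- C * (0.85 / max(W %*% C))
  # Class named explicitly: a "C =" argument would otherwise partially
  # match new()'s Class formal
  new(Class = "GroundTruth", W = W,
      groupTemplates = list(healthy = .unitCols(tmplH), CAI = .unitCols(tmplC)),
      weightSd = list(healthy = sdH, CAI = sdC),
      C = C, muscleNames = muscles, snrDb = snrDb, seed = as.integer(seed))
}

#' Simulate one subject's landing trials
#'
#' Draws the subject's synergy vectors as the group template plus per-cell
#' Gaussian weight jitter (clipped at zero, columns renormalized), then per
#' trial scales each module's activation profile by log-normal amplitude
#' jitter and forms V = W C. Noise is multiplicative log-normal plus
#' additive Gaussian, split evenly in power and calibrated per muscle row
#' so every muscle's signal-to-noise ratio equals `snrDb` (after MVC
#' normalization, channel noise scales with the muscle's activity level);
#' entries are clipped to `[0, 1]`.
#'
#' @param gt a [GroundTruth-class].
#' @param group `"CAI"` or `"healthy"`.
#' @param subjectSeed RNG seed for this subject.
#' @param snrDb signal-to-noise ratio in dB (default from `gt`).
#' @param nTrials trials per subject (default 3).
#' @param subjectId identifier.
#' @return list with `subjectId`, `group`, `Wtrue` (the subject's generating
#'   vectors) and `trials` (list of [ActivationMatrix-class]).
#' @export
synthesizeSubject <- function(gt, group = c("healthy", "CAI"),
                              subjectSeed = 1L, snrDb = gt@snrDb,
                              nTrials = 3, subjectId = "S1") {
  group <- match.arg(group)
  stopifnot(!is.na(snrDb))   # snrDb = Inf gives the noise-free model
  set.seed(subjectSeed)
  tmpl <- gt@groupTemplates[[group]]
  sdW <- gt@weightSd[[group]]
  k <- ncol(tmpl)
  # weights floored at a small positive value so no muscle is ever fully
  # silent (physiological crosstalk/baseline; also keeps per-muscle VAF
  # well-defined)
  Wsub <- pmax(tmpl + matrix(rnorm(length(tmpl), 0, 1) * sdW,
                             nrow(tmpl), k), 0.005)
  Wsub <- .unitCols(Wsub)
  rownames(Wsub) <- gt@muscleNames
  noiseVar <- 10^(-snrDb / 10)
  sigMult <- sqrt(noiseVar / 2)
  trials <- lapply(seq_len(nTrials), function(tr) {
    amp <- exp(rnorm(k, 0, 0.1))
    V0 <- Wsub %*% (gt@C * amp)
    sigAdd <- sqrt(noiseVar / 2 * rowMeans(V0^2))   # per-muscle noise floor
    V <- V0 * exp(matrix(rnorm(length(V0), 0, sigMult), nrow(V0))) +
      matrix(rnorm(length(V0), 0, 1), nrow(V0)) * sigAdd
    ActivationMatrix(pmin(pmax(V, 0), 1), muscleNames = gt@muscleNames,
                     subjectId = subjectId, group = group,
                     trialIndex = as.integer(tr))
  })
  list(subjectId = subjectId, group = group, Wtrue = Wsub, trials = trials)
}

#' Simulate a full two-group landing study
#'
#' @param nPerGroup subjects per group (default 22).
#' @param nTrials trials per subject (default 3).
#' @param snrDb signal-to-noise ratio in dB (default 20).
#' @param seed master seed; per-subject seeds are derived from it, so the
#'   whole dataset is reproducible from (arguments, seed).
#' @param gt optional [GroundTruth-class]; built with defaults otherwise.
#' @return A [SyntheticDataset-class].
#' @export
synthesizeDataset <- function(nPerGroup = 22, nTrials = 3, snrDb = 20,
                              seed = 1L, gt = NULL) {
  if (is.null(gt)) gt <- makeGroundTruth(snrDb = snrDb)
  set.seed(seed)
  nTotal <- 2L * nPerGroup
  subSeeds <- sample.int(.Machine$integer.max - 1L, nTotal)
  groups <- rep(c("CAI", "healthy"), each = nPerGroup)
  ids <- paste0(rep(c("CAI", "H"), each = nPerGroup),
                sprintf("%02d", rep(seq_len(nPerGroup), 2)))
  subjects <- lapply(seq_len(nTotal), function(i) {
    synthesizeSubject(gt, groups[i], subjectSeed = subSeeds[i],
                      snrDb = snrDb, nTrials = nTrials, subjectId = ids[i])
  })
  new("SyntheticDataset", subjects = subjects, groundTruth = gt,
      seed = as.integer(seed), snrDb = snrDb)
}

#' Synthesize raw sEMG from an activation envelope
#'
#' Produces a raw-EMG-like trace per muscle: a 30-450 Hz band-limited
#' Gaussian carrier amplitude-modulated by the (upsampled) envelope, plus a
#' 50 Hz mains component and additive baseline noise. The construction is
#' such that [preprocessEMG()] followed by [mvcNormalize()] recovers the
#' envelope (correlation > 0.95 at default settings).
#'
#' @param envelope matrix (muscles x phase points) with entries in `[0, 1]`,
#'   or an [ActivationMatrix-class].
#' @param fs sampling rate in Hz (default 1000).
#' @param durationS trial duration in seconds (default 1).
#' @param seed RNG seed.
#' @param mainsAmp amplitude of the 50 Hz interference (default 0.05).
#' @param baselineSd SD of additive baseline noise (default 0.01).
#' @param ... metadata passed to [EMGRecording()].
#' @return A raw-stage [EMGRecording-class] (`fs * durationS` samples).
#' @export
synthesizeRawEMG <- function(envelope, fs = 1000, durationS = 1, seed = 1L,
                             mainsAmp = 0.05, baselineSd = 0.01, ...) {
  if (is(envelope, "ActivationMatrix")) {
    muscles <- muscleNames(envelope)
    envelope <- activationValues(envelope)
  } else {
    muscles <- rownames(envelope)
  }
  if (min(envelope) < 0 || max(envelope) > 1)
    stop("envelope must lie in [0, 1]")
  n <- round(fs * durationS)
  envUp <- timeNormalize(t(envelope), n)   # n x muscles
  set.seed(seed)
  bf <- signal::butter(4, c(30, 450) / (fs / 2), type = "pass")
  tt <- seq_len(n) / fs
  raw <- apply(envUp, 2, function(e) {
    carrier <- signal::filtfilt(bf$b, bf$a, rnorm(n))
    carrier <- carrier / sd(carrier)
    e * carrier + mainsAmp * sin(2 * pi * 50 * tt) + rnorm(n, 0, baselineSd)
  })
  EMGRecording(raw, fs = fs, muscleNames = muscles, stage = "raw", ...)
}

#' Synthesize a raw MVC recording
#'
#' Maximal-contraction trace: constant envelope at 100% for every muscle,
#' through the same raw-EMG construction as [synthesizeRawEMG()].
#'
#' @param muscles channel labels.
#' @param fs sampling rate in Hz.
#' @param durationS duration in seconds (default 2).
#' @param seed RNG seed.
#' @param ... passed to [synthesizeRawEMG()].
#' @return A raw-stage [EMGRecording-class].
#' @export
synthesizeMVCRecording <- function(muscles = defaultMuscles(), fs = 1000,
                                   durationS = 2, seed = 1L, ...) {
  env <- matrix(1, length(muscles), 101, dimnames = list(muscles, NULL))
  synthesizeRawEMG(env, fs = fs, durationS = durationS, seed = seed, ...)
}
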