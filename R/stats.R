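## Group statistics: assumption-routed two-sample tests with Cohen's d on
## synergy weights, and permutation-based 1-D statistical parametric
## mapping (SPM) on activation-coefficient curves.

#' Assumption-routed two-sample test
#'
#' Shapiro-Wilk normality on each group and Levene's test (deviations from
#' the group mean) for variance homogeneity, both at level `alpha`. When all
#' three pass, an independent two-sample t-test with pooled variance is
#' used; otherwise the Wilcoxon rank-sum test (exact when both n <= 25 and
#' there are no ties, normal approximation with tie correction otherwise).
#' All tests are two-sided.
#'
#' @param x1,x2 numeric samples, each of length >= 3.
#' @param alpha level for the assumption checks and reported tests
#'   (default 0.05).
#' @return `list(test = "t" | "wilcoxon", p, statistic, shapiroP = c(p1, p2),
#'   leveneP)`.
#' @export
routeAndTest <- function(x1, x2, alpha = 0.05) {
  if (length(x1) < 3 || length(x2) < 3)
    stop("each group needs at least 3 observations")
  if (sd(x1) == 0 && sd(x2) == 0)
    stop("both groups have zero variance; no test applicable")
  sw1 <- if (sd(x1) > 0) shapiro.test(x1)$p.value else 0
  sw2 <- if (sd(x2) > 0) shapiro.test(x2)$p.value else 0
  grp <- factor(rep(c("a", "b"), c(length(x1), length(x2))))
  lev <- car::leveneTest(c(x1, x2) ~ grp, center = mean)[["Pr(>F)"]][1]
  if (sw1 > alpha && sw2 > alpha && lev > alpha) {
    ht <- t.test(x1, x2, var.equal = TRUE)
    list(test = "t", p = ht$p.value, statistic = unname(ht$statistic),
         shapiroP = c(sw1, sw2), leveneP = lev)
  } else {
    exact <- length(x1) <= 25 && length(x2) <= 25 &&
      !anyDuplicated(c(x1, x2))
    ht <- suppressWarnings(wilcox.test(x1, x2, exact = exact, correct = TRUE))
    list(test = "wilcoxon", p = ht$p.value, statistic = unname(ht$statistic),
         shapiroP = c(sw1, sw2), leveneP = lev)
  }
}

#' Cohen's d from summary statistics
#'
#' d = (mean1 - mean2) / s_p with the pooled standard deviation
#' s_p = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)).
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return Signed effect size d.
#' @examples
#' cohensDStats(0.50, 0.25, 22, 0.32, 0.13, 22)  # 0.903
#' @export
cohensDStats <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean1 - mean2) / sp
}

#' Cohen's d from raw samples
#'
#' @param x1,x2 numeric samples.
#' @return Signed effect size d.
#' @export
cohensD <- function(x1, x2) {
  cohensDStats(mean(x1), sd(x1), length(x1), mean(x2), sd(x2), length(x2))
}

#' Effect-size label
#'
#' Conventional bands: |d| < 0.2 small, 0.2-0.5 medium, 0.5-0.8
#' medium-large, >= 0.8 large.
#'
#' @param d effect size.
#' @return Character label.
#' @export
effectSizeLabel <- function(d) {
  a <- abs(d)
  ifelse(a < 0.2, "small",
         ifelse(a < 0.5, "medium",
                ifelse(a < 0.8, "medium-large", "large")))
}

.pointwiseT <- function(S1, Q1, S2, Q2, n1, n2) {
  # pooled-variance two-sample t from per-node sums and sums of squares
  m1 <- S1 / n1; m2 <- S2 / n2
  v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (Q2 - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

.runs <- function(flag) {
  # maximal runs of TRUE: data.frame(start, end) in index units
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Permutation-based 1-D SPM comparison of curve sets
#'
#' Computes the pooled-variance two-sample t statistic at each phase node,
#' then a field-wide critical threshold as the (1 - alpha) quantile of the
#' maximum absolute t over random group-label permutations (the observed
#' labeling included). Maximal runs of |t| above the threshold form
#' supra-threshold clusters; each cluster's p-value is the permutation tail
#' probability of a supra-threshold run at least as long.
#'
#' @param curves1,curves2 matrices, subjects x phase nodes (same node count).
#' @param alpha field-wide significance level (default 0.05).
#' @param nPerm number of permutations (default 10000; a warning is issued
#'   below 100).
#' @param seed RNG seed.
#' @return A list of class `"SPMResult"`: `tCurve`, `threshold`, `clusters`
#'   (data.frame startPct, endPct, extent, p), `alpha`, `nPerm`,
#'   `method = "permutation"`.
#' @export
spmCompareCurves <- function(curves1, curves2, alpha = 0.05, nPerm = 10000,
                             seed = 1L) {
  curves1 <- as.matrix(curves1); curves2 <- as.matrix(curves2)
  n1 <- nrow(curves1); n2 <- nrow(curves2)
  if (n1 < 3 || n2 < 3) stop("need at least 3 curves per group")
  if (ncol(curves1) != ncol(curves2)) stop("node counts differ")
  if (nPerm < 100) warning("nPerm < 100: threshold will be unreliable")
  X <- rbind(curves1, curves2)
  if (any(apply(X, 2, sd) == 0))
    stop("degenerate (constant) node across all curves")
  N <- n1 + n2; Tn <- ncol(X)
  set.seed(seed)
  # B x N group-1 indicator; first row = observed labeling
  Z <- matrix(0, nPerm, N)
  Z[1, seq_len(n1)] <- 1
  for (b in 2:nPerm) Z[b, sample.int(N, n1)] <- 1
  X2 <- X^2
  S1 <- Z %*% X;  Q1 <- Z %*% X2
  S2 <- matrix(colSums(X), nPerm, Tn, byrow = TRUE) - S1
  Q2 <- matrix(colSums(X2), nPerm, Tn, byrow = TRUE) - Q1
  Tmat <- abs(.pointwiseT(S1, Q1, S2, Q2, n1, n2))
  tObs <- .pointwiseT(S1[1, ], Q1[1, ], S2[1, ], Q2[1, ], n1, n2)
  maxT <- apply(Tmat, 1, max)
  thr <- sort(maxT)[ceiling((1 - alpha) * nPerm)]
  supra <- abs(tObs) > thr
  clusters <- data.frame(startPct = numeric(), endPct = numeric(),
                         extent = integer(), p = numeric())
  if (any(supra)) {
    obsRuns <- .runs(supra)
    # permutation distribution of the maximal supra-threshold run length
    permExtent <- apply(Tmat > thr, 1, function(f) {
      if (!any(f)) 0L else max(rle(f)$lengths[rle(f)$values])
    })
    pct <- seq(0, 100, length.out = Tn)
    clusters <- data.frame(
      startPct = pct[obsRuns$start], endPct = pct[obsRuns$end],
      extent = obsRuns$end - obsRuns$start + 1L,
      p = vapply(obsRuns$end - obsRuns$start + 1L,
                 function(e) mean(permExtent >= e), numeric(1)))
  }
  structure(list(tCurve = tObs, threshold = thr, clusters = clusters,
                 alpha = alpha, nPerm = nPerm, method = "permutation"),
            class = "SPMResult")
}

#' Table of per-muscle weight comparisons between groups
#'
#' For every reference synergy and muscle, gathers the classified subjects'
#' synergy-vector weights in each group (one column per subject per
#' reference: the best-correlated classified synergy), then applies
#' [routeAndTest()] and [cohensD()].
#'
#' @param matchA,matchB [SynergyMatch-class] objects for the two groups
#'   (e.g. CAI-like and healthy-like), classified against the same
#'   reference set.
#' @param alpha level passed to the routed test.
#' @return data.frame with one row per (reference synergy, muscle):
#'   means/SDs/n per group, test used, p, d, and effect-size label. A
#'   reference synergy absent from either group is skipped with a warning.
#' @export
compareGroupWeights <- function(matchA, matchB, alpha = 0.05) {
  wA <- .weightsByReference(matchA)
  wB <- .weightsByReference(matchB)
  refs <- intersect(names(wA), names(wB))
  skipped <- setdiff(union(names(wA), names(wB)), refs)
  if (length(skipped))
    warning("reference synergy absent in one group, skipped: ",
            paste(skipped, collapse = ", "))
  out <- list()
  for (rf in refs) {
    A <- wA[[rf]]; B <- wB[[rf]]
    for (mIdx in seq_len(nrow(A))) {
      x1 <- A[mIdx, ]; x2 <- B[mIdx, ]
      rt <- routeAndTest(x1, x2, alpha)
      d <- cohensD(x1, x2)
      out[[length(out) + 1L]] <- data.frame(
        refSynergy = as.integer(rf), muscle = rownames(A)[mIdx],
        meanA = mean(x1), sdA = sd(x1), nA = length(x1),
        meanB = mean(x2), sdB = sd(x2), nB = length(x2),
        test = rt$test, p = rt$p, d = d, effect = effectSizeLabel(d))
    }
  }
  do.call(rbind, out)
}

.weightsByReference <- function(match) {
  # per reference id: muscles x subjects matrix of classified weights,
  # taking each subject's best-correlated classified synergy
  tab <- matchTable(match)
  D <- match@pool@D
  tab$column <- seq_len(nrow(tab))
  tab <- tab[tab$classified, ]
  out <- list()
  for (rf in sort(unique(tab$bestRef))) {
    sub <- tab[tab$bestRef == rf, ]
    sub <- sub[order(sub$subject, -sub$r), ]
    sub <- sub[!duplicated(sub$subject), ]
    if (nrow(sub) >= 3)
      out[[as.character(rf)]] <- D[, sub$column, drop = FALSE]
  }
  out
}

#' Per-reference SPM comparison of activation-coefficient curves
#'
#' For each reference synergy present in both groups, compares the matched
#' subjects' trial-averaged activation-coefficient curves with
#' [spmCompareCurves()].
#'
#' @inheritParams compareGroupWeights
#' @param nPerm,seed passed to [spmCompareCurves()].
#' @return Named list of `"SPMResult"` objects, one per reference synergy id.
#' @export
compareGroupCoefficients <- function(matchA, matchB, alpha = 0.05,
                                     nPerm = 10000, seed = 1L) {
  cA <- .curvesByReference(matchA)
  cB <- .curvesByReference(matchB)
  refs <- intersect(names(cA), names(cB))
  out <- list()
  for (rf in refs)
    out[[rf]] <- spmCompareCurves(cA[[rf]], cB[[rf]], alpha = alpha,
                                  nPerm = nPerm, seed = seed)
  out
}

.curvesByReference <- function(match) {
  tab <- matchTable(match)
  curves <- match@pool@coefficients
  tab$column <- seq_len(nrow(tab))
  tab <- tab[tab$classified, ]
  out <- list()
  for (rf in sort(unique(tab$bestRef))) {
    sub <- tab[tab$bestRef == rf, ]
    sub <- sub[order(sub$subject, -sub$r), ]
    sub <- sub[!duplicated(sub$subject), ]
    if (nrow(sub) >= 3)
      out[[as.character(rf)]] <- curves[sub$column, , drop = FALSE]
  }
  out
}
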