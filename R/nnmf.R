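## Synergy extraction: Lee-Seung multiplicative-update NMF on the
## non-negative activation matrix V (muscles x concatenated phase points),
## V ~ W C, with dual-VAF selection of the synergy number.

#' Frobenius reconstruction loss
#'
#' Squared Frobenius norm of the residual, `sum((V - W C)^2)`, the cost
#' function minimized by the multiplicative updates.
#'
#' @param V non-negative data matrix (muscles x points).
#' @param W,C current factors.
#' @return Scalar loss.
#' @export
nmfLoss <- function(V, W, C) sum((V - W %*% C)^2)

#' One multiplicative update of W and C
#'
#' The standard Lee-Seung updates for the Frobenius objective, applied
#' sequentially (C is updated with the already-updated W):
#' `W <- W * (V C') / (W C C' + eps)`, then
#' `C <- C * (W' V) / (W' W C + eps)`.
#' Both updates preserve non-negativity and never increase the loss.
#'
#' @param V non-negative data matrix.
#' @param W,C non-negative factors of conformable shape.
#' @param eps small constant guarding the denominators.
#' @return `list(W = , C = )` with the updated factors.
#' @export
nmfUpdateStep <- function(V, W, C, eps = 1e-12) {
  if (nrow(W) != nrow(V) || ncol(C) != ncol(V) || ncol(W) != nrow(C))
    stop("non-conformable shapes for V = W C")
  if (min(V) < 0 || min(W) < 0 || min(C) < 0)
    stop("V, W, C must be non-negative")
  W <- W * (V %*% t(C)) / (W %*% (C %*% t(C)) + eps)
  C <- C * (t(W) %*% V) / ((t(W) %*% W) %*% C + eps)
  list(W = W, C = C)
}

#' Global variance accounted for
#'
#' `1 - ||V - W C||_F^2 / ||V||_F^2`: the fraction of the data's squared
#' signal reconstructed by the factorization.
#'
#' @inheritParams nmfLoss
#' @return Scalar fraction (1 for perfect reconstruction).
#' @export
vafGlobal <- function(V, W, C) {
  denom <- sum(V^2)
  if (denom == 0) stop("VAF undefined for an all-zero matrix")
  1 - nmfLoss(V, W, C) / denom
}

#' Per-muscle (local) variance accounted for
#'
#' The global VAF formula applied row-wise, one value per muscle.
#'
#' @inheritParams nmfLoss
#' @return Named numeric vector, one fraction per row of `V`. Rows of `V`
#'   that are identically zero yield `NA` with a warning.
#' @export
vafLocal <- function(V, W, C) {
  R <- V - W %*% C
  denom <- rowSums(V^2)
  out <- 1 - rowSums(R^2) / denom
  if (any(denom == 0)) {
    warning("local VAF undefined for all-zero muscle row(s)")
    out[denom == 0] <- NA_real_
  }
  names(out) <- rownames(V)
  out
}

.normalizeColumns <- function(W, C) {
  # unit-norm columns of W, compensating row scaling of C (W C unchanged)
  nrm <- sqrt(colSums(W^2))
  pos <- nrm > 0
  W[, pos] <- sweep(W[, pos, drop = FALSE], 2, nrm[pos], "/")
  C[pos, ] <- sweep(C[pos, , drop = FALSE], 1, nrm[pos], "*")
  list(W = W, C = C)
}

#' NNMF synergy decomposition
#'
#' Factorizes a non-negative activation matrix into `k` synergy vectors and
#' activation coefficients by multiplicative updates, restarted from
#' `nRestarts` random initializations (uniform in (0, 1]); the restart with
#' the lowest Frobenius loss wins. Columns of the returned `W` are
#' normalized to unit Euclidean norm with compensating scaling of `C`, so
#' the product W C (and hence every VAF) is unchanged.
#'
#' @param V non-negative matrix, muscles x points (trials concatenated
#'   column-wise).
#' @param k number of synergies, `1 <= k <= nrow(V)`.
#' @param seed RNG seed; identical seed and inputs give identical output.
#' @param nRestarts number of random restarts (default 20).
#' @param maxIter maximum update iterations per restart (default 1000).
#' @param tol relative loss-change convergence tolerance (default 1e-6).
#' @param eps denominator guard (default 1e-12).
#' @param subjectId,group provenance carried into the result.
#' @return A [SynergyDecomposition-class].
#' @export
nnmfDecompose <- function(V, k, seed = 1L, nRestarts = 20, maxIter = 1000,
                          tol = 1e-6, eps = 1e-12,
                          subjectId = NA_character_, group = NA_character_) {
  V <- as.matrix(V)
  if (min(V) < 0) stop("V must be non-negative")
  m <- nrow(V); n <- ncol(V)
  if (k < 1 || k > m) stop("k must lie in 1..nrow(V)")
  if (any(rowSums(V^2) == 0))
    warning("V has all-zero muscle row(s); their local VAF will be NA")
  best <- NULL
  set.seed(seed)
  for (r in seq_len(nRestarts)) {
    W0 <- matrix(1 - runif(m * k), m, k)   # uniform in (0, 1]
    C0 <- matrix(1 - runif(k * n), k, n)
    fit <- .nmfMuCpp(V, W0, C0, as.integer(maxIter), tol, eps)
    if (is.null(best) || tail(fit$lossTrace, 1) < tail(best$lossTrace, 1))
      best <- fit
  }
  nc <- .normalizeColumns(best$W, best$C)
  rownames(nc$W) <- rownames(V)
  vl <- suppressWarnings(vafLocal(V, nc$W, nc$C))
  # Class named explicitly: a "C =" argument would otherwise partially
  # match new()'s Class formal
  new(Class = "SynergyDecomposition",
      W = nc$W, C = nc$C, k = as.integer(k),
      vafGlobal = vafGlobal(V, nc$W, nc$C),
      vafLocal = vl,
      lossTrace = best$lossTrace,
      seed = as.integer(seed), nRestarts = as.integer(nRestarts),
      converged = isTRUE(best$converged),
      subjectId = as.character(subjectId), group = as.character(group))
}

#' Dual-VAF selection of the synergy number
#'
#' Iterates k = 1, 2, ... and selects the first k whose global VAF reaches
#' `vafGlobalMin` while every per-muscle VAF reaches `vafLocalMin`
#' (comparisons at a 1e-12 margin, i.e. ">= threshold"). When no k up to
#' `kMax` qualifies, `nopt = kMax` is returned with `thresholdsMet = FALSE`.
#'
#' @param V non-negative activation matrix.
#' @param kMax largest synergy number to consider (default `nrow(V)`).
#' @param vafGlobalMin global VAF threshold (default 0.90).
#' @param vafLocalMin per-muscle VAF threshold (default 0.75).
#' @param computeAll also decompose for k > nopt up to kMax (default FALSE;
#'   selection stops at the first qualifying k).
#' @inheritParams nnmfDecompose
#' @return A [SynergyRankSelection-class].
#' @export
selectSynergyNumber <- function(V, kMax = nrow(V), vafGlobalMin = 0.90,
                                vafLocalMin = 0.75, seed = 1L,
                                nRestarts = 20, maxIter = 1000, tol = 1e-6,
                                computeAll = FALSE,
                                subjectId = NA_character_,
                                group = NA_character_) {
  if (kMax > nrow(V)) stop("kMax cannot exceed the muscle count")
  margin <- 1e-12
  decomps <- list()
  tab <- data.frame(k = integer(), vafGlobal = numeric(),
                    minVafLocal = numeric())
  nopt <- NA_integer_
  for (k in seq_len(kMax)) {
    d <- nnmfDecompose(V, k, seed = seed, nRestarts = nRestarts,
                       maxIter = maxIter, tol = tol,
                       subjectId = subjectId, group = group)
    decomps[[k]] <- d
    minLocal <- min(d@vafLocal, na.rm = TRUE)
    tab <- rbind(tab, data.frame(k = k, vafGlobal = d@vafGlobal,
                                 minVafLocal = minLocal))
    if (is.na(nopt) &&
        d@vafGlobal >= vafGlobalMin - margin &&
        minLocal >= vafLocalMin - margin) {
      nopt <- k
      if (!computeAll) break
    }
  }
  met <- !is.na(nopt)
  if (!met) nopt <- as.integer(kMax)
  new("SynergyRankSelection",
      nopt = as.integer(nopt), thresholdsMet = met, vafTable = tab,
      decompositions = decomps,
      vafGlobalMin = vafGlobalMin, vafLocalMin = vafLocalMin)
}
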