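## Reference-synergy construction: pooled synergy vectors are clustered by
## K-means (Lloyd iterations with an explicit distortion trace), the cluster
## count picked by mean silhouette, and every subject synergy classified
## against the centroids by Pearson correlation.

#' Pool synergy vectors across subjects
#'
#' Stacks the synergy-vector columns of per-subject decompositions into one
#' muscles x k_total matrix with provenance, carrying the trial-averaged
#' activation-coefficient curve of each synergy.
#'
#' @param decompositions list of [SynergyDecomposition-class] objects.
#' @param nPoints phase points per trial (default 101); each coefficient row
#'   (trials concatenated) is reshaped and averaged across trials.
#' @param muscles row labels; defaults to those of the first decomposition.
#' @return A [SynergyPool-class].
#' @export
buildSynergyPool <- function(decompositions, nPoints = 101, muscles = NULL) {
  stopifnot(length(decompositions) > 0)
  Ds <- lapply(decompositions, synergyVectors)
  if (is.null(muscles)) {
    muscles <- rownames(Ds[[1]])
    if (is.null(muscles)) muscles <- paste0("M", seq_len(nrow(Ds[[1]])))
  }
  D <- do.call(cbind, Ds)
  prov <- do.call(rbind, lapply(decompositions, function(d) {
    data.frame(subject = d@subjectId, group = d@group,
               synergyIndex = seq_len(d@k))
  }))
  curves <- do.call(rbind, lapply(decompositions, function(d) {
    t(apply(d@C, 1, function(row) {
      nTrials <- length(row) / nPoints
      if (nTrials == floor(nTrials) && nTrials >= 1)
        rowMeans(matrix(row, nrow = nPoints))
      else timeNormalize(row, nPoints)
    }))
  }))
  rownames(D) <- muscles
  new("SynergyPool", D = D, provenance = prov, coefficients = curves,
      muscleNames = muscles)
}

#' K-means clustering of synergy vectors
#'
#' Lloyd's algorithm on the columns of `D`: assign each point to the nearest
#' centroid by squared Euclidean distance (ties to the lowest cluster index),
#' recompute centroids as cluster means, and stop when the distortion
#' J = sum of squared point-to-assigned-centroid distances changes by less
#' than `tol`. An emptied cluster is re-seeded at the point farthest from
#' its assigned centroid. The best of `nInit` random initializations
#' (centroids drawn from distinct data points) is returned.
#'
#' @param D muscles x k_total matrix; columns are the points clustered.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nInit random initializations (default 50).
#' @param maxIter Lloyd iterations per initialization (default 300).
#' @param tol absolute tolerance on the distortion change (default 1e-8).
#' @return `list(assignment, centroids, distortion, trace)`; `trace` is the
#'   distortion after each iteration of the winning initialization.
#' @export
kmeansCluster <- function(D, k, seed = 1L, nInit = 50, maxIter = 300,
                          tol = 1e-8) {
  X <- t(D)                       # points x dims
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must lie in 1..ncol(D)")
  set.seed(seed)
  best <- NULL
  for (init in seq_len(nInit)) {
    mu <- X[sample.int(n, k), , drop = FALSE]
    trace <- numeric()
    assign <- rep(1L, n)
    for (iter in seq_len(maxIter)) {
      d2 <- .sqDistToCentroids(X, mu)
      assign <- max.col(-d2, ties.method = "first")
      # re-seed each empty cluster at the point farthest from its assigned
      # centroid, never stealing the last member of another cluster
      ownDist <- d2[cbind(seq_len(n), assign)]
      repeat {
        empty <- which(tabulate(assign, k) == 0L)
        if (!length(empty)) break
        movable <- tabulate(assign, k)[assign] > 1L
        far <- which(movable)[which.max(ownDist[movable])]
        assign[far] <- empty[1]
        ownDist[far] <- -Inf
      }
      for (j in seq_len(k))
        mu[j, ] <- colMeans(X[assign == j, , drop = FALSE])
      J <- max(0, sum(.sqDistToCentroids(X, mu)[cbind(seq_len(n), assign)]))
      trace <- c(trace, J)
      if (iter > 1 && abs(trace[iter - 1] - J) < tol) break
    }
    if (is.null(best) || tail(trace, 1) < best$distortion)
      best <- list(assignment = assign, centroids = t(mu),
                   distortion = tail(trace, 1), trace = trace)
  }
  rownames(best$centroids) <- rownames(D)
  best
}

.sqDistToCentroids <- function(X, mu) {
  # n x k matrix of squared Euclidean distances
  outer(rowSums(X^2), rep(1, nrow(mu))) - 2 * X %*% t(mu) +
    outer(rep(1, nrow(X)), rowSums(mu^2))
}

#' Per-point silhouette values
#'
#' For each point, S = (b - a) / max(a, b), with `a` the mean Euclidean
#' distance to the other members of its own cluster and `b` the smallest
#' over other clusters of the mean distance to that cluster's members.
#' Points in singleton clusters, and points with a = b = 0, score 0.
#'
#' @param D matrix whose columns are the clustered points.
#' @param assignment integer cluster id per column of `D`.
#' @return Numeric vector of silhouette values in `[-1, 1]`.
#' @export
silhouetteValues <- function(D, assignment) {
  ids <- sort(unique(assignment))
  if (length(ids) < 2) stop("silhouette requires at least 2 clusters")
  X <- t(D)
  n <- nrow(X)
  dm <- as.matrix(dist(X))
  vapply(seq_len(n), function(i) {
    own <- assignment == assignment[i]
    if (sum(own) == 1) return(0)           # singleton convention
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(ids[ids != assignment[i]], function(j) {
      mean(dm[i, assignment == j])
    }, numeric(1)))
    if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

#' Mean silhouette coefficient
#'
#' @inheritParams silhouetteValues
#' @return Scalar in `[-1, 1]`.
#' @export
silhouetteMean <- function(D, assignment) mean(silhouetteValues(D, assignment))

#' Silhouette-optimal cluster count and reference synergies
#'
#' Runs [kmeansCluster()] for each candidate cluster count and keeps the one
#' maximizing the mean silhouette coefficient (ties broken toward the
#' smallest count). The winning centroids become the reference synergies.
#'
#' @param D muscles x k_total pooled synergy-vector matrix.
#' @param kRange candidate cluster counts (default 2:8).
#' @param seed RNG seed.
#' @param nInit random initializations per count (default 50).
#' @return A [ReferenceSynergySet-class].
#' @export
selectClusterNumber <- function(D, kRange = 2:8, seed = 1L, nInit = 50) {
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2) || any(kRange > ncol(D) - 1))
    stop("cluster counts must lie in 2..(ncol(D) - 1)")
  fits <- list()
  sil <- numeric(length(kRange))
  for (idx in seq_along(kRange)) {
    fits[[idx]] <- kmeansCluster(D, kRange[idx], seed = seed + idx,
                                 nInit = nInit)
    sil[idx] <- silhouetteMean(D, fits[[idx]]$assignment)
  }
  bestIdx <- which.max(sil)   # which.max takes the first (smallest k) on ties
  fit <- fits[[bestIdx]]
  new("ReferenceSynergySet",
      centroids = fit$centroids, assignment = as.integer(fit$assignment),
      distortion = fit$distortion, silhouetteMean = sil[bestIdx],
      silhouetteTable = data.frame(k = kRange, silhouette = sil),
      chosenK = kRange[bestIdx],
      muscleNames = if (is.null(rownames(D))) character() else rownames(D))
}

#' Classify pooled synergies against reference centroids
#'
#' Computes the Pearson correlation of every pooled synergy vector with
#' every reference centroid; a synergy is assigned to its best-correlated
#' centroid when r exceeds `rMin`, otherwise left unclassified. Attached
#' activation-coefficient curves inherit the assignment.
#'
#' @param pool a [SynergyPool-class] (same muscle ordering as the reference).
#' @param refs a [ReferenceSynergySet-class].
#' @param rMin classification threshold on r (default 0.6, strict ">").
#' @return A [SynergyMatch-class].
#' @export
matchToReference <- function(pool, refs, rMin = 0.6) {
  stopifnot(is(pool, "SynergyPool"), is(refs, "ReferenceSynergySet"))
  if (length(refs@muscleNames) && length(pool@muscleNames) &&
      !identical(pool@muscleNames, refs@muscleNames))
    stop("muscle ordering of pool and reference set differ")
  D <- pool@D
  R <- matrix(NA_real_, ncol(D), ncol(refs@centroids))
  degenerate <- apply(D, 2, sd) == 0
  if (any(degenerate))
    warning("zero-variance synergy vector(s): left unclassified")
  ok <- !degenerate
  if (any(ok)) R[ok, ] <- cor(D[, ok, drop = FALSE], refs@centroids)
  bestRef <- ifelse(ok, max.col(replace(R, is.na(R), -Inf), ties.method = "first"),
                    NA_integer_)
  bestR <- R[cbind(seq_len(nrow(R)), ifelse(is.na(bestRef), 1L, bestRef))]
  bestR[!ok] <- NA_real_
  classified <- !is.na(bestR) & bestR > rMin
  tab <- cbind(pool@provenance,
               data.frame(bestRef = as.integer(bestRef), r = bestR,
                          classified = classified))
  new("SynergyMatch", table = tab, rMatrix = R, pool = pool, rMin = rMin)
}

#' Per-group similarity rate
#'
#' Percentage of pooled subject synergies classified against the reference
#' set (r above threshold), reported per group.
#'
#' @param match a [SynergyMatch-class].
#' @return Named numeric vector of percentages (0-100) per group.
#' @export
similarityRate <- function(match) {
  tab <- matchTable(match)
  rates <- 100 * vapply(split(tab$classified, tab$group), mean, numeric(1))
  rates[sort(names(rates))]
}
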