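test_that("K-means attains zero distortion with one cluster per point", {
  set.seed(1)
  D <- matrix(runif(3 * 5), 3, 5)   # 5 distinct points
  fit <- kmeansCluster(D, 5, seed = 2, nInit = 10)
  expect_equal(fit$distortion, 0, tolerance = 1e-12)
  expect_identical(sort(unique(fit$assignment)), 1:5)
})

test_that("K-means separates two well-separated clouds like the exact optimum", {
  set.seed(3)
  pts <- cbind(matrix(rnorm(8, 0, 0.1), 2, 4),
               matrix(rnorm(8, 5, 0.1), 2, 4))
  fit <- kmeansCluster(pts, 2, seed = 4, nInit = 10)
  truth <- rep(1:2, each = 4)
  agree <- max(mean(fit$assignment == truth), mean(fit$assignment == 3 - truth))
  expect_equal(agree, 1)

  # brute-force oracle: enumerate all 2-partitions of the 8 points
  best <- Inf
  for (mask in 1:(2^8 - 2)) {
    lab <- as.integer(intToBits(mask))[1:8]
    if (length(unique(lab)) < 2) next
    J <- sum(sapply(0:1, function(g) {
      P <- pts[, lab == g, drop = FALSE]
      if (!ncol(P)) return(0)
      sum((P - rowMeans(P))^2)
    }))
    best <- min(best, J)
  }
  expect_equal(fit$distortion, best, tolerance = 1e-9)

  # and it agrees with the reference implementation's optimum
  km <- kmeans(t(pts), 2, nstart = 10)
  expect_equal(fit$distortion, km$tot.withinss, tolerance = 1e-9)
})

test_that("K-means distortion is non-increasing across Lloyd iterations", {
  D <- matrix(runif(4 * 30), 4, 30)
  for (k in c(2, 4, 6)) {
    fit <- kmeansCluster(D, k, seed = k, nInit = 5)
    expect_true(all(diff(fit$trace) <= 1e-10))
    expect_lte(fit$distortion, fit$trace[1])
  }
})

test_that("silhouette values match hand evaluation and stay in [-1, 1]", {
  D <- matrix(c(0, 0.1, 10, 10.1), nrow = 1)
  s <- silhouetteValues(D, c(1, 1, 2, 2))
  expect_equal(s[1], (10.05 - 0.1) / 10.05, tolerance = 1e-12)  # ~0.990
  expect_equal(s[3], (9.95 - 0.1) / 9.95, tolerance = 1e-12)

  # all points identical: a = b = 0 scores 0 by convention
  same <- matrix(1, 2, 6)
  expect_equal(silhouetteMean(same, rep(1:2, 3)), 0)

  # bounded on random data, and matching the reference implementation
  set.seed(9)
  D <- matrix(runif(3 * 24), 3, 24)
  cl <- sample(1:3, 24, replace = TRUE)
  cl[1:3] <- 1:3   # ensure non-empty clusters
  s <- silhouetteValues(D, cl)
  expect_true(all(s >= -1 & s <= 1))
  ref <- cluster::silhouette(cl, dist(t(D)))
  expect_equal(s, unname(ref[, "sil_width"]), tolerance = 1e-12)

  expect_error(silhouetteValues(D, rep(1, 24)), "at least 2")
})

test_that("silhouette is invariant to relabeling and global scaling", {
  set.seed(10)
  D <- matrix(runif(4 * 20), 4, 20)
  cl <- rep(1:4, each = 5)
  s0 <- silhouetteMean(D, cl)
  relab <- c(3L, 1L, 4L, 2L)[cl]
  expect_equal(silhouetteMean(D, relab), s0, tolerance = 1e-12)
  expect_equal(silhouetteMean(5 * D, cl), s0, tolerance = 1e-12)
})

test_that("cluster-number selection finds the generating archetype count", {
  arch4 <- makeGroundTruth()@groupTemplates$healthy
  D4 <- archetypePool(arch4, perArch = 12, sd = 0.05, seed = 21)
  ref4 <- selectClusterNumber(D4, kRange = 2:8, seed = 5, nInit = 20)
  expect_identical(ref4@chosenK, 4L)
  # centroids recover the archetypes (cosine > 0.95 at low noise)
  cs <- abs(crossprod(
    sweep(referenceCentroids(ref4), 2,
          sqrt(colSums(referenceCentroids(ref4)^2)), "/"), arch4))
  expect_true(all(apply(cs, 2, max) > 0.95))

  arch2 <- arch4[, c(1, 3)]
  D2 <- archetypePool(arch2, perArch = 12, sd = 0.05, seed = 22)
  ref2 <- selectClusterNumber(D2, kRange = 2:8, seed = 6, nInit = 20)
  expect_identical(ref2@chosenK, 2L)

  # reproducible under a fixed seed
  again <- selectClusterNumber(D4, kRange = 2:8, seed = 5, nInit = 20)
  expect_identical(ref4@silhouetteTable, again@silhouetteTable)
  expect_identical(ref4@assignment, again@assignment)
})

test_that("Pearson matching classifies by best correlated centroid", {
  gt <- makeGroundTruth()
  arch <- gt@groupTemplates$healthy
  refs <- new("ReferenceSynergySet", centroids = arch,
              assignment = rep(1:4, 3), distortion = 1,
              silhouetteMean = 0.8,
              silhouetteTable = data.frame(k = 4, silhouette = 0.8),
              chosenK = 4L, muscleNames = rownames(arch))

  mkPool <- function(D) new("SynergyPool", D = D,
    provenance = data.frame(subject = paste0("s", seq_len(ncol(D))),
                            group = "healthy",
                            synergyIndex = 1L),
    coefficients = matrix(0.5, ncol(D), 101), muscleNames = rownames(arch))

  # a centroid matches itself with r = 1
  m <- matchToReference(mkPool(arch[, 1, drop = FALSE]), refs)
  expect_equal(matchTable(m)$r, 1, tolerance = 1e-12)
  expect_identical(matchTable(m)$bestRef, 1L)
  expect_true(matchTable(m)$classified)

  # a weight pattern matching no module stays unclassified (r > 0.6 rule)
  odd <- c(SL = 1, MG = 0.01, LG = 0.01, TA = 0.9, PL = 0.01, RF = 0.01,
           VM = 0.9, VL = 0.01, BF = 0.01, GM = 0.9)[rownames(arch)]
  odd <- matrix(odd / sqrt(sum(odd^2)), 10, 1, dimnames = list(rownames(arch)))
  modd <- matchToReference(mkPool(odd), refs)
  expect_false(matchTable(modd)$classified)
  expect_lt(matchTable(modd)$r, 0.6)

  # small perturbations (sd 0.05) stay assigned to their centroid
  hits <- 0L
  for (sdd in 1:100) {
    set.seed(sdd)
    j <- sample(1:4, 1)
    v <- arch[, j] + rnorm(10, 0, 0.05)
    mv <- matchToReference(mkPool(matrix(v, 10, 1,
                                         dimnames = list(rownames(arch)))), refs)
    hits <- hits + (matchTable(mv)$bestRef == j && matchTable(mv)$classified)
  }
  expect_identical(hits, 100L)

  # permutation-equivariance in centroid order
  perm <- c(3, 1, 4, 2)
  refsP <- initialize(refs, centroids = arch[, perm])
  pool <- mkPool(archetypePool(arch, 2, sd = 0.05, seed = 30))
  m1 <- matchTable(matchToReference(pool, refs))
  m2 <- matchTable(matchToReference(pool, refsP))
  expect_identical(order(perm)[m1$bestRef], m2$bestRef)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)

  # zero-variance vectors warn and stay unclassified
  zv <- matrix(0, 10, 1, dimnames = list(rownames(arch)))
  expect_warning(mz <- matchToReference(mkPool(zv), refs), "zero-variance")
  expect_false(matchTable(mz)$classified)
})

test_that("similarity rates are per-group percentages of classified synergies", {
  tab <- data.frame(subject = rep(c("a", "b"), each = 2),
                    group = rep(c("CAI", "healthy"), each = 2),
                    synergyIndex = rep(1:2, 2),
                    bestRef = 1L, r = 0.9,
                    classified = c(TRUE, TRUE, FALSE, FALSE))
  m <- new("SynergyMatch", table = tab, rMatrix = matrix(0.9, 4, 1),
           pool = new("SynergyPool", D = matrix(1, 3, 4),
                      provenance = tab[, 1:3],
                      coefficients = matrix(0, 4, 101),
                      muscleNames = c("x", "y", "z")),
           rMin = 0.6)
  expect_equal(similarityRate(m), c(CAI = 100, healthy = 0))
})
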