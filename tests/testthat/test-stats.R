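test_that("Cohen's d reproduces published effect sizes from summary stats", {
  expect_equal(round(cohensDStats(0.50, 0.25, 22, 0.32, 0.13, 22), 3), 0.903)
  expect_equal(round(cohensDStats(0.64, 0.31, 22, 0.48, 0.22, 22), 3), 0.595)
  expect_equal(round(cohensDStats(0.45, 0.17, 22, 0.31, 0.15, 22), 3), 0.873)
  expect_equal(round(abs(cohensDStats(0.08, 0.07, 22, 0.22, 0.15, 22)), 3),
               1.196)
})

test_that("Cohen's d is antisymmetric and guards degenerate inputs", {
  set.seed(1)
  x1 <- rnorm(15); x2 <- rnorm(12, 0.5)
  expect_equal(cohensD(x1, x2), -cohensD(x2, x1), tolerance = 1e-12)
  # matches the pooled-SD formula computed by hand
  sp <- sqrt((14 * var(x1) + 11 * var(x2)) / 25)
  expect_equal(cohensD(x1, x2), (mean(x1) - mean(x2)) / sp, tolerance = 1e-12)
  expect_error(cohensDStats(1, 0, 5, 1, 0, 5), "pooled standard deviation")
  expect_error(cohensDStats(1, 1, 1, 0, 1, 5), "n >= 2")

  expect_identical(effectSizeLabel(c(0.1, 0.3, 0.6, 1.2)),
                   c("small", "medium", "medium-large", "large"))
})

test_that("assumption routing picks t for clean data, Wilcoxon for skew", {
  set.seed(2)
  base <- rnorm(22)
  rt <- routeAndTest(base, base + 1e-9)
  expect_identical(rt$test, "t")
  expect_gt(rt$p, 0.999)

  # t route matches the textbook pooled-variance formula
  x1 <- rnorm(20); x2 <- rnorm(20, 0.4)
  rt2 <- routeAndTest(x1, x2)
  if (rt2$test == "t") {
    sp2 <- (19 * var(x1) + 19 * var(x2)) / 38
    tstat <- (mean(x1) - mean(x2)) / sqrt(sp2 * (2 / 20))
    expect_equal(rt2$p, 2 * pt(-abs(tstat), 38), tolerance = 1e-9)
  }

  # strongly skewed samples at n = 22 get the rank-sum route
  set.seed(4)
  wilcoxTaken <- 0L
  for (i in 1:10) {
    y1 <- rexp(22); y2 <- rexp(22)
    wilcoxTaken <- wilcoxTaken + (routeAndTest(y1, y2)$test == "wilcoxon")
  }
  expect_gte(wilcoxTaken, 8L)

  # exact rank-sum p for small untied samples matches the exact distribution
  set.seed(5)
  z1 <- rnorm(8); z2 <- rnorm(9, 2)
  rt3 <- routeAndTest(exp(z1), exp(z2))  # lognormal: wilcoxon route
  if (rt3$test == "wilcoxon") {
    U <- sum(rank(c(exp(z1), exp(z2)))[1:8]) - 8 * 9 / 2
    pExact <- 2 * min(pwilcox(U, 8, 9), 1 - pwilcox(U - 1, 8, 9))
    expect_equal(rt3$p, min(1, pExact), tolerance = 1e-9)
  }

  expect_error(routeAndTest(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(routeAndTest(1:2, 1:5), "at least 3")
})

test_that("the pointwise SPM statistic equals the classic two-sample t", {
  set.seed(6)
  c1 <- matrix(rnorm(10 * 101), 10)
  c2 <- matrix(rnorm(12 * 101, 0.3), 12)
  res <- spmCompareCurves(c1, c2, nPerm = 200, seed = 1)
  node <- 37
  tt <- t.test(c1[, node], c2[, node], var.equal = TRUE)
  expect_equal(res$tCurve[node], unname(tt$statistic), tolerance = 1e-10)
  expect_gt(res$threshold, 0)
})

test_that("SPM finds no effect on label-permuted identical data", {
  set.seed(7)
  X <- matrix(rnorm(20 * 101), 20)
  X <- X[sample(20), ]
  res <- spmCompareCurves(X[1:10, ], X[11:20, ], alpha = 0.05,
                          nPerm = 500, seed = 2)
  expect_identical(nrow(res$clusters), 0L)
})

test_that("SPM detects a mid-phase group shift where it was injected", {
  set.seed(8)
  n <- 22
  base <- sin(seq(0, pi, length.out = 101))
  mk <- function(shift) t(replicate(n, base + rnorm(101, 0, 0.3))) +
    matrix(rep(shift, each = n), n)
  shift <- numeric(101)
  shift[51:81] <- 0.45    # >= 1 SD over 50-80% of the phase
  res <- spmCompareCurves(mk(shift), mk(0 * shift), alpha = 0.05,
                          nPerm = 1000, seed = 3)
  expect_gt(nrow(res$clusters), 0)
  overlaps <- any(res$clusters$startPct <= 80 & res$clusters$endPct >= 50)
  expect_true(overlaps)
  expect_lt(min(res$clusters$p), 0.05)

  expect_warning(spmCompareCurves(mk(shift), mk(0 * shift), nPerm = 50,
                                  seed = 1), "nPerm")
  expect_error(spmCompareCurves(mk(shift)[1:2, ], mk(0 * shift), nPerm = 200),
               "at least 3")
})

test_that("group weight comparison flags an injected GM shift in module 1", {
  gt <- makeGroundTruth()
  arch <- gt@groupTemplates$healthy
  refs <- new("ReferenceSynergySet", centroids = arch,
              assignment = rep(1:4, 2), distortion = 1, silhouetteMean = 0.8,
              silhouetteTable = data.frame(k = 4, silhouette = 0.8),
              chosenK = 4L, muscleNames = rownames(arch))
  mkPool <- function(D, prov) new("SynergyPool", D = D, provenance = prov,
                                  coefficients = matrix(0.5, ncol(D), 101),
                                  muscleNames = rownames(arch))
  mkGroup <- function(n, gmDelta, seed, label) {
    set.seed(seed)
    cols <- list(); prov <- list()
    for (i in seq_len(n)) for (j in 1:4) {
      v <- pmax(arch[, j] + rnorm(10, 0, 0.06), 0)
      if (j == 1) v["GM"] <- v["GM"] + gmDelta
      cols[[length(cols) + 1]] <- v / sqrt(sum(v^2))
      prov[[length(prov) + 1]] <- data.frame(subject = paste0(label, i),
                                             group = label, synergyIndex = j)
    }
    mkPool(do.call(cbind, cols), do.call(rbind, prov))
  }
  mA <- matchToReference(mkGroup(22, 0.2, 41, "CAI"), refs)
  mB <- matchToReference(mkGroup(22, 0, 42, "healthy"), refs)
  tab <- compareGroupWeights(mA, mB)

  # full grid: 10 muscles x 4 reference synergies
  expect_identical(nrow(tab), 40L)
  gm1 <- tab[tab$refSynergy == 1 & tab$muscle == "GM", ]
  expect_lt(gm1$p, 0.05)
  expect_gt(gm1$d, 0.8)
  expect_identical(gm1$effect, "large")
})

test_that("null groups produce roughly nominal false-positive rates", {
  gt <- makeGroundTruth()
  arch <- gt@groupTemplates$healthy
  refs <- new("ReferenceSynergySet", centroids = arch,
              assignment = rep(1:4, 2), distortion = 1, silhouetteMean = 0.8,
              silhouetteTable = data.frame(k = 4, silhouette = 0.8),
              chosenK = 4L, muscleNames = rownames(arch))
  mkGroup <- function(n, seed, label) {
    set.seed(seed)
    cols <- list(); prov <- list()
    for (i in seq_len(n)) for (j in 1:4) {
      v <- pmax(arch[, j] + rnorm(10, 0, 0.06), 0)
      cols[[length(cols) + 1]] <- v / sqrt(sum(v^2))
      prov[[length(prov) + 1]] <- data.frame(subject = paste0(label, i),
                                             group = label, synergyIndex = j)
    }
    new("SynergyPool", D = do.call(cbind, cols),
        provenance = do.call(rbind, prov),
        coefficients = matrix(0.5, length(cols), 101),
        muscleNames = rownames(arch))
  }
  ps <- unlist(lapply(1:5, function(r) {
    mA <- matchToReference(mkGroup(22, 100 + r, "CAI"), refs)
    mB <- matchToReference(mkGroup(22, 200 + r, "healthy"), refs)
    compareGroupWeights(mA, mB)$p
  }))
  # 200 null cells: the rejection rate should sit near alpha
  expect_lt(mean(ps < 0.05), 0.12)
})
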