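test_that("an exact factorization is a fixed point of the update step", {
  set.seed(1)
  W <- matrix(runif(10 * 3, 0.1, 1), 10, 3)
  C <- matrix(runif(3 * 40, 0.1, 1), 3, 40)
  V <- W %*% C
  up <- nmfUpdateStep(V, W, C)
  expect_equal(up$W, W, tolerance = 1e-8)
  expect_equal(up$C, C, tolerance = 1e-8)
})

test_that("multiplicative updates never increase the reconstruction loss", {
  V <- randNonneg(10, 101, seed = 2)
  set.seed(3)
  W <- matrix(runif(10 * 4), 10, 4); C <- matrix(runif(4 * 101), 4, 101)
  losses <- numeric(200)
  for (i in 1:200) {
    st <- nmfUpdateStep(V, W, C)
    W <- st$W; C <- st$C
    losses[i] <- nmfLoss(V, W, C)
  }
  expect_true(all(diff(losses) <= 1e-12 * losses[-length(losses)]))

  # and the compiled path records the same monotone trace property
  d <- nnmfDecompose(V, 4, seed = 1, nRestarts = 3)
  tr <- lossTrace(d)
  expect_true(all(diff(tr) <= 1e-12 * tr[-length(tr)]))
})

test_that("the compiled update loop equals iterated R update steps", {
  V <- randNonneg(8, 30, seed = 9)
  set.seed(10)
  W0 <- matrix(runif(8 * 3), 8, 3); C0 <- matrix(runif(3 * 30), 3, 30)
  cpp <- emgsynergy:::.nmfMuCpp(V, W0, C0, 50L, -1, 1e-12)
  W <- W0; C <- C0
  for (i in 1:50) { st <- nmfUpdateStep(V, W, C); W <- st$W; C <- st$C }
  expect_equal(cpp$W, W, tolerance = 1e-10)
  expect_equal(cpp$C, C, tolerance = 1e-10)
  expect_equal(utils::tail(cpp$lossTrace, 1), nmfLoss(V, W, C),
               tolerance = 1e-10)
})

test_that("VAF formulas match hand and brute-force evaluation", {
  # perfect reconstruction
  W <- matrix(c(1, 2), 2, 1); C <- matrix(c(1, 3), 1, 2)
  expect_equal(vafGlobal(W %*% C, W, C), 1)
  expect_equal(unname(vafLocal(W %*% C, W, C)), c(1, 1))

  # hand-computed case: residual energy 16, signal energy 30
  V <- matrix(c(1, 3, 2, 4), 2, 2)
  Wid <- diag(2); Cz <- matrix(c(1, 3, 2, 0), 2, 2)
  expect_equal(vafGlobal(V, Wid, Cz), 1 - 16 / 30, tolerance = 1e-12)
  expect_equal(unname(vafLocal(V, Wid, Cz)), c(1, 1 - 16 / 25),
               tolerance = 1e-12)

  # zero reconstruction
  expect_equal(vafGlobal(V, Wid, Cz * 0), 0)
  # one perfectly reconstructed row, one zeroed-out row
  Chalf <- rbind(Cz[1, ], 0)
  expect_equal(unname(vafLocal(V, Wid, Chalf)), c(1, 0))

  # row-wise brute force on a random case
  set.seed(12)
  V <- randNonneg(3, 20); W <- randNonneg(3, 2, 13); C <- randNonneg(2, 20, 14)
  brute <- sapply(1:3, function(i) {
    r <- V[i, ] - (W %*% C)[i, ]
    1 - sum(r^2) / sum(V[i, ]^2)
  })
  expect_equal(unname(vafLocal(V, W, C)), brute, tolerance = 1e-12)

  expect_error(vafGlobal(matrix(0, 2, 2), Wid, Cz), "all-zero")
})

test_that("decomposition recovers exact low-rank structure and ground truth", {
  # rank-1 non-negative matrix
  set.seed(20)
  V1 <- outer(runif(6, 0.1, 1), runif(40, 0.1, 1))
  d1 <- nnmfDecompose(V1, 1, seed = 1, nRestarts = 5)
  expect_gt(vafGlobalOf(d1), 0.999)

  # four known modules, low noise: matched cosines above 0.90
  gt <- makeGroundTruth()
  s <- synthesizeSubject(gt, "healthy", subjectSeed = 31, snrDb = 30)
  V <- assembleDataMatrix(s$trials)
  d <- nnmfDecompose(V, 4, seed = 2)
  expect_gt(bestPermCosine(synergyVectors(d), s$Wtrue), 0.90)

  # unit-norm synergy columns with the product unchanged
  expect_equal(unname(sqrt(colSums(synergyVectors(d)^2))), rep(1, 4),
               tolerance = 1e-9)
})

test_that("decomposition is deterministic and scale-invariant", {
  V <- randNonneg(6, 50, seed = 33)
  d1 <- nnmfDecompose(V, 3, seed = 7, nRestarts = 5)
  d2 <- nnmfDecompose(V, 3, seed = 7, nRestarts = 5)
  expect_identical(synergyVectors(d1), synergyVectors(d2))
  expect_identical(activationCoefficients(d1), activationCoefficients(d2))

  # scaling V scales the factorization consistently and leaves VAFs unchanged
  W1 <- synergyVectors(d1); C1 <- activationCoefficients(d1)
  expect_equal(vafGlobal(10 * V, W1, 10 * C1), vafGlobalOf(d1),
               tolerance = 1e-12)
  expect_equal(vafLocal(10 * V, W1, 10 * C1), vafLocalOf(d1),
               tolerance = 1e-12)
  # the update trajectory is scale-equivariant from scaled initializations
  set.seed(8)
  W0 <- matrix(runif(18), 6, 3); C0 <- matrix(runif(150), 3, 50)
  a <- emgsynergy:::.nmfMuCpp(V, W0, C0, 40L, -1, 1e-12)
  b <- emgsynergy:::.nmfMuCpp(4 * V, 2 * W0, 2 * C0, 40L, -1, 1e-12)
  expect_equal(b$W, 2 * a$W, tolerance = 1e-8)
  expect_equal(b$C, 2 * a$C, tolerance = 1e-8)
})

test_that("global VAF is near-monotone in the synergy number", {
  V <- assembleDataMatrix(
    synthesizeSubject(makeGroundTruth(), "healthy", 41, snrDb = 20)$trials)
  vafs <- sapply(1:6, function(k)
    vafGlobalOf(nnmfDecompose(V, k, seed = 5, nRestarts = 10)))
  expect_true(all(diff(vafs) >= -0.005))
})

test_that("dual-VAF selection picks the smallest qualifying synergy number", {
  # exact rank-1 matrix
  set.seed(50)
  V1 <- outer(runif(6, 0.1, 1), runif(40, 0.1, 1))
  sel1 <- selectSynergyNumber(V1, kMax = 4, seed = 1, nRestarts = 5)
  expect_identical(noptSynergies(sel1), 1L)
  expect_true(sel1@thresholdsMet)

  # the 90% / 75% dual thresholds are the defaults
  expect_equal(eval(formals(selectSynergyNumber)$vafGlobalMin), 0.90)
  expect_equal(eval(formals(selectSynergyNumber)$vafLocalMin), 0.75)

  # forced under-selection is flagged
  V <- assembleDataMatrix(
    synthesizeSubject(makeGroundTruth(), "healthy", 52, snrDb = 20)$trials)
  sel2 <- selectSynergyNumber(V, kMax = 2, seed = 1, nRestarts = 10)
  expect_false(sel2@thresholdsMet)
  expect_identical(noptSynergies(sel2), 2L)

  expect_warning(nnmfDecompose(rbind(V1, 0), 2, seed = 1, nRestarts = 2),
                 "all-zero")
})
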