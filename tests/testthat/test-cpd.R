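test_that("exact rank-one tensors are fitted perfectly", {
  set.seed(1)
  a <- abs(rnorm(5)); b <- abs(rnorm(4)); d <- abs(rnorm(3))
  W <- array(outer(outer(a, b), d), c(5, 4, 3))
  m <- nncpALS(W, decomposeConfig(rank = 1, seed = 1))
  expect_equal(fitPercent(m), 100, tolerance = 1e-6)
  expect_true(all(vapply(factorMatrices(m), function(u) all(u >= 0),
                         logical(1))))
  expect_error(nncpALS(array(0, c(3, 3, 3)), decomposeConfig(rank = 1)),
               "all-zero")
})

test_that("the ALS objective is non-increasing at every sweep", {
  fx <- genericCPTensor(c(7, 6, 5, 4), rank = 3, seed = 2, noiseSigma = 0.1)
  m <- nncpALS(fx$W, decomposeConfig(rank = 3, seed = 3, nRestarts = 1,
                                     maxIterations = 60, tol = 1e-12))
  expect_monotone_trace(m)
})

test_that("decomposition is deterministic given the seed", {
  fx <- genericCPTensor(c(6, 5, 4, 3), rank = 2, seed = 4, noiseSigma = 0.05)
  cfg <- decomposeConfig(rank = 2, seed = 9, nRestarts = 2)
  m1 <- nncpALS(fx$W, cfg)
  m2 <- nncpALS(fx$W, cfg)
  expect_identical(factorMatrices(m1), factorMatrices(m2))
})

test_that("explained variance matches its definition and a brute-force oracle", {
  fx <- genericCPTensor(c(5, 4, 3), rank = 2, seed = 5)
  m <- nncpALS(fx$W, decomposeConfig(rank = 2, seed = 1))
  expect_equal(explainedVariance(m, fx$W), 100, tolerance = 1e-6)

  zeroModel <- m
  zeroModel@factors <- lapply(m@factors, function(u) u * 0)
  expect_equal(explainedVariance(zeroModel, fx$W), 0)
  expect_error(explainedVariance(m, array(0, c(5, 4, 3))), "zero-norm")

  # orthogonally decomposable rank-3 tensor (disjoint supports): a rank-2
  # model captures exactly the top-2 weights; oracle = direct residual norm
  blocks <- cbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0),
                  c(0, 0, 0, 0, 1, 1)) / sqrt(2)
  sig <- c(3, 2, 1)
  U <- list(blocks, blocks, sweep(blocks, 2, sig, "*"))
  W <- makeCPTensor(U)
  m2 <- nncpALS(W, decomposeConfig(rank = 2, seed = 2, nRestarts = 6))
  oracle <- 100 * (sig[1]^2 + sig[2]^2) / sum(sig^2)
  expect_equal(explainedVariance(m2, W), oracle, tolerance = 1e-6)
})

test_that("CORCONDIA is 100 for well-specified models and collapses when over-factored", {
  fx <- genericCPTensor(c(8, 7, 6, 5, 4), rank = 3, seed = 6)
  m3 <- nncpALS(fx$W, decomposeConfig(rank = 3, seed = 2))
  expect_equal(fitPercent(m3), 100, tolerance = 1e-6)
  expect_equal(corcondia(m3, fx$W), 100, tolerance = 1e-2)

  # self-consistency: any model scored on its own exact reconstruction
  recon <- makeCPTensor(factorMatrices(m3))
  expect_equal(corcondia(m3, recon), 100, tolerance = 1e-4)

  # rank-3 fit of an exact rank-2 tensor: core far from superdiagonal,
  # oracle = dense least-squares core on a small 6 x 5 x 4 tensor
  fx2 <- genericCPTensor(c(6, 5, 4), rank = 2, seed = 7, noiseSigma = 0.02)
  m <- nncpALS(fx2$W, decomposeConfig(rank = 3, seed = 3, nRestarts = 4))
  ccFast <- tryCatch(corcondia(m, fx2$W), error = function(e) e)
  if (!inherits(ccFast, "error")) {
    U <- factorMatrices(m)
    K <- U[[3]] %x% U[[2]] %x% U[[1]]
    G <- array(qr.solve(K, as.vector(fx2$W)), c(3, 3, 3))
    Tc <- array(0, c(3, 3, 3)); Tc[cbind(1:3, 1:3, 1:3)] <- 1
    ccDense <- 100 * (1 - sum((G - Tc)^2) / 3)
    expect_equal(ccFast, ccDense, tolerance = 1e-6)
    expect_lt(ccFast, 50)
  } else {
    expect_match(conditionMessage(ccFast), "lower rank")
  }
})

test_that("compressed CORCONDIA equals the dense least-squares core", {
  fx <- genericCPTensor(c(5, 4, 3), rank = 2, seed = 8, noiseSigma = 0.1)
  m <- nncpALS(fx$W, decomposeConfig(rank = 2, seed = 1))
  U <- factorMatrices(m)
  K <- U[[3]] %x% U[[2]] %x% U[[1]]
  G <- array(qr.solve(K, as.vector(fx$W)), c(2, 2, 2))
  Tc <- array(0, c(2, 2, 2)); Tc[cbind(1:2, 1:2, 1:2)] <- 1
  ccDense <- 100 * (1 - sum((G - Tc)^2) / 2)
  expect_equal(corcondia(m, fx$W), ccDense, tolerance = 1e-6)
})

test_that("canonical normalisation moves all scale to the last mode", {
  fx <- genericCPTensor(c(5, 4, 3, 3), rank = 2, seed = 9, noiseSigma = 0.05)
  m <- nncpALS(fx$W, decomposeConfig(rank = 2, seed = 1))
  nm <- normalizeModel(m)
  expect_equal(makeCPTensor(factorMatrices(nm)),
               makeCPTensor(factorMatrices(m)), tolerance = 1e-12)
  for (j in 1:3)
    expect_equal(unname(sqrt(colSums(factorMatrices(nm)[[j]]^2))), rep(1, 2))
  # idempotence
  expect_equal(factorMatrices(normalizeModel(nm)), factorMatrices(nm),
               tolerance = 1e-14)
  # scale transfer: doubling a spatial column doubles the condition loading
  m2 <- nm
  m2@factors[[1]][, 1] <- 2 * m2@factors[[1]][, 1]
  nm2 <- normalizeModel(m2)
  expect_equal(nm2@factors[[4]][, 1], 2 * nm@factors[[4]][, 1],
               tolerance = 1e-12)
  expect_equal(nm2@factors[[1]], nm@factors[[1]], tolerance = 1e-12)
  # zero column is refused by name
  m3 <- m
  m3@factors[[2]][, 2] <- 0
  expect_error(normalizeModel(m3), "component 2 in mode 2")
})

test_that("rank sweep tabulates diagnostics with comparable seeds", {
  cfg0 <- smallSimConfig(seed = 12L)
  gt <- makeGroundTruth(cfg0)
  W <- synthTensor5D(gt, cfg0)
  cfg <- decomposeConfig(rank = 1, seed = 5, nRestarts = 2,
                         maxIterations = 200, tol = 1e-7)
  tab <- sweepRank(W, ranks = 1:4, cfg = cfg)
  expect_identical(dim(tab), c(4L, 3L))
  # explained variance non-decreasing up to restart noise
  expect_true(all(diff(tab$explained_variance) > -0.2))
  expect_identical(nrow(sweepRank(W, ranks = 3, cfg = cfg)), 1L)

  # exact generic rank-3 tensor: CORCONDIA ~100 at rank 3, collapsed (or
  # rank-deficient, reported NA) at rank 4
  fx <- genericCPTensor(c(8, 7, 6, 5), rank = 3, seed = 13)
  tab2 <- sweepRank(fx$W, ranks = 3:4, cfg = cfg)
  expect_equal(tab2$corcondia[1], 100, tolerance = 1e-2)
  expect_true(is.na(tab2$corcondia[2]) || tab2$corcondia[2] < 50)
})

test_that("congruence matching recovers identity, orthogonality and permutations", {
  fx <- genericCPTensor(c(6, 5, 4), rank = 3, seed = 14)
  m <- normalizeModel(nncpALS(fx$W, decomposeConfig(rank = 3, seed = 2)))
  self <- congruence(m, m)
  expect_identical(self$matching, 1:3)
  expect_equal(unname(self$matched), rep(1, 3), tolerance = 1e-12)

  # orthogonal (disjoint-support) factors: off-diagonal congruence zero
  blocks <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)) / sqrt(2)
  U <- list(blocks, blocks, blocks)
  phi <- congruence(U, U)$matrix
  expect_equal(unname(phi - diag(2)), matrix(0, 2, 2), tolerance = 1e-12)

  # permuted-component copy: matching recovers the permutation
  perm <- c(3L, 1L, 2L)
  mPerm <- m
  mPerm@factors <- lapply(m@factors, function(u) u[, perm, drop = FALSE])
  cg <- congruence(m, mPerm)
  expect_identical(cg$matching, perm)
  expect_equal(unname(cg$matched), rep(1, 3), tolerance = 1e-12)

  bad <- m
  bad@factors[[1]][, 1] <- 0
  expect_error(congruence(bad, m), "zero column")
})

test_that("unconstrained ALS attains the exhaustive multi-start fit on tiny tensors", {
  fx <- genericCPTensor(c(5, 4, 3, 3, 2), rank = 2, seed = 15,
                        noiseSigma = 0.05)
  base <- decomposeConfig(rank = 2, seed = 3, nonneg = FALSE)
  many <- decomposeConfig(rank = 2, seed = 101, nonneg = FALSE,
                          nRestarts = 20L)
  f1 <- fitPercent(nncpALS(fx$W, base))
  f2 <- fitPercent(nncpALS(fx$W, many))
  expect_gte(f1, f2 - 1e-6)
})

test_that("fixed modes are never touched by the fit", {
  fx <- genericCPTensor(c(6, 5, 4, 3, 3), rank = 2, seed = 16,
                        noiseSigma = 0.05)
  init <- lapply(dim(fx$W), function(d) abs(matrix(rnorm(d * 2), d, 2)))
  init[1:3] <- fx$U[1:3]
  cfg <- decomposeConfig(rank = 2, seed = 1, fixedModes = 1:3, init = init)
  m <- nncpALS(fx$W, cfg)
  for (j in 1:3) expect_identical(factorMatrices(m)[[j]], fx$U[[j]])
  expect_error(nncpALS(fx$W, decomposeConfig(rank = 2, fixedModes = 1:3)),
               "requires a provided init")
})

test_that("noisy study-shaped tensors are recovered component by component", {
  cfg0 <- smallSimConfig(seed = 21L)   # 5% noise by default
  gt <- makeGroundTruth(cfg0)
  W <- synthTensor5D(gt, cfg0)
  m <- normalizeModel(nncpALS(W, decomposeConfig(rank = 3, seed = 7,
                                                 nRestarts = 3)))
  cg <- congruence(m, groundTruthModel(gt))
  expect_gte(min(cg$matched), 0.95)
})
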