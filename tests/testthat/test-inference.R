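makeStore <- function(gt, cfg, noise = 0.01, seed = 1L) {
  # per-subject/condition TFRTensor cells sliced from a synthetic tensor
  W <- synthTensor5D(gt, cfg)
  vals <- tensorValues(W)
  store <- list()
  for (s in seq_along(W@subjects)) {
    cell <- list()
    for (co in seq_along(W@conditionLabels))
      cell[[W@conditionLabels[co]]] <- new("TFRTensor",
        values = vals[, , , s, co], channels = W@channels, freqs = W@freqs,
        times = W@times, subject = W@subjects[s],
        condition = W@conditionLabels[co], nTrials = 10L, nUndefined = 0L)
    store[[W@subjects[s]]] <- cell
  }
  store
}

test_that("model tensors are stacked with the contrast's label order", {
  cfg <- smallSimConfig(seed = 31L, nSubjects = 3L)
  gt <- makeGroundTruth(cfg)
  store <- makeStore(gt, cfg)
  cm <- contrastModel(2)
  W <- buildModelTensor(store, cm)
  expect_identical(dim(tensorValues(W)), c(8L, 6L, 10L, 3L, 4L))
  expect_identical(conditionLabels(W), conditionSet(2))

  # slab values sit where their labels say, independent of insertion order
  Wrev <- buildModelTensor(store[rev(names(store))], cm)
  for (s in names(store))
    expect_equal(
      tensorValues(W)[, , , match(s, W@subjects), ],
      tensorValues(Wrev)[, , , match(s, Wrev@subjects), ])

  # missing cells and axis mismatches are named
  broken <- store
  broken[["S02"]][["post-LEV"]] <- NULL
  expect_error(buildModelTensor(broken, cm), "S02.*post-LEV")
  broken2 <- store
  broken2[["S01"]][["pre-LEV"]]@freqs <- broken2[["S01"]][["pre-LEV"]]@freqs + 1
  expect_error(buildModelTensor(broken2, cm), "axis mismatch")
})

test_that("contrast models carry the study condition sets", {
  expect_identical(conditionLabels(contrastModel(2)),
                   c("pre-LEV", "post-LEV", "pre-LTG", "post-LTG"))
  expect_identical(conditionLabels(contrastModel(3)),
                   c("pre-placebo", "post-placebo", "pre-LEV", "post-LEV"))
  expect_length(contrastModel(2)@betweenDrug, 2L)
  expect_length(contrastModel(1)@betweenDrug, 0L)
  expect_error(contrastModel(7), "modelId")
})

test_that("slab permutation preserves slab contents and is uniform", {
  cfg <- smallSimConfig(seed = 32L, nSubjects = 3L)
  gt <- makeGroundTruth(cfg)
  W <- synthTensor5D(gt, cfg)
  # identity permutation returns the input unchanged
  expect_identical(tensorValues(permuteTensor(W, perm = seq_len(12))),
                   tensorValues(W))
  # the multiset of slab norms is invariant under any permutation
  slabNorms <- function(x) {
    v <- tensorValues(x); d <- dim(v)
    sort(sqrt(colSums(matrix(v, prod(d[1:3]))^2)))
  }
  set.seed(5)
  expect_equal(slabNorms(permuteTensor(W)), slabNorms(W), tolerance = 1e-12)

  # uniformity: over many draws each slab visits each position ~ 1/(S*C)
  tiny <- tensor5D(array(1:4, c(1, 1, 1, 2, 2)))
  set.seed(42)
  nDraw <- 4000
  counts <- matrix(0, 4, 4)
  for (i in seq_len(nDraw)) {
    v <- as.vector(tensorValues(permuteTensor(tiny)))
    counts[cbind(v, 1:4)] <- counts[cbind(v, 1:4)] + 1
  }
  expect_lt(max(abs(counts / nDraw - 0.25)), 0.025)  # ~3.6 binomial SDs
})

test_that("refitting on the unpermuted tensor is a fixed point with frozen modes", {
  cfg <- smallSimConfig(seed = 33L)
  gt <- makeGroundTruth(cfg)
  W <- synthTensor5D(gt, cfg)
  master <- masterDecomposition(W, decomposeConfig(rank = 3, seed = 2,
                                                   nRestarts = 2))
  rf <- refitLoadings(W, master)
  scale <- max(factorMatrices(master)[[5]])
  expect_lt(max(abs(factorMatrices(rf)[[5]] - factorMatrices(master)[[5]])) /
              scale, 1e-6)
  for (j in 1:3)
    expect_identical(factorMatrices(rf)[[j]], factorMatrices(master)[[j]])
  expect_error(refitLoadings(W, nncpALS(W, decomposeConfig(rank = 3, seed = 2))),
               "canonical")
})

test_that("the projected-array shortcut equals the naive full-tensor refit", {
  cfg <- smallSimConfig(seed = 34L, nSubjects = 4L)
  gt <- makeGroundTruth(cfg)
  W <- synthTensor5D(gt, cfg)
  master <- masterDecomposition(W, decomposeConfig(rank = 3, seed = 3,
                                                   nRestarts = 2))
  set.seed(8)
  Wp <- permuteTensor(W)
  short <- refitLoadings(Wp, master, maxIter = 500L, tol = 1e-15)
  naive <- normalizeModel(nncpALS(Wp, decomposeConfig(
    rank = 3, seed = 1, fixedModes = 1:3, init = factorMatrices(master),
    maxIterations = 500L, tol = 1e-15)))
  expect_equal(factorMatrices(short)[[5]], factorMatrices(naive)[[5]],
               tolerance = 1e-8)
  expect_equal(factorMatrices(short)[[4]], factorMatrices(naive)[[4]],
               tolerance = 1e-8)
})

test_that("permutation test is reproducible, respects the p floor and its decisions", {
  cfg <- smallSimConfig(seed = 35L)
  gt <- makeGroundTruth(cfg)
  W <- synthTensor5D(gt, cfg)
  master <- masterDecomposition(W, decomposeConfig(rank = 3, seed = 4,
                                                   nRestarts = 2))
  cm <- contrastModel(2)
  pt <- permutationTest(W, master, cm, nPerm = 99, seed = 11)
  pt2 <- permutationTest(W, master, cm, nPerm = 99, seed = 11)
  expect_identical(resultTable(pt), resultTable(pt2))
  expect_identical(nrow(nullSamples(pt)), 99L)

  tab <- resultTable(pt)
  expect_true(all(tab$p >= 1 / 100))
  expect_true(all(tab$p <= 1))

  # decision contract: outside the empirical 2.5/97.5% null quantiles
  qlo <- apply(nullSamples(pt), 2, quantile, probs = 0.025, type = 1)
  qhi <- apply(nullSamples(pt), 2, quantile, probs = 0.975, type = 1)
  expect_identical(tab$decision,
                   unname(tab$observed < qlo | tab$observed > qhi))

  expect_warning(permutationTest(W, master, cm, nPerm = 20, seed = 1),
                 "nPerm")
})

test_that("a noiseless no-effect tensor gives p = 1 everywhere", {
  cfg <- smallSimConfig(seed = 36L, noiseSigma = 0, effectSpec = c(1, 1, 1))
  gt <- makeGroundTruth(cfg)
  W <- synthTensor5D(gt, cfg)
  master <- masterDecomposition(W, decomposeConfig(rank = 3, seed = 5,
                                                   nRestarts = 2))
  pt <- suppressWarnings(
    permutationTest(W, master, contrastModel(2), nPerm = 50, seed = 2))
  tab <- resultTable(pt)
  # every condition slab is identical: observed differences sit at the null
  # median (zero), p is 1 and nothing is rejected
  expect_equal(tab$observed, rep(0, nrow(tab)), tolerance = 1e-5)
  expect_true(all(tab$p > 0.99))
  expect_false(any(tab$decision))
})

test_that("an injected drug effect is detected on the affected component only", {
  cfg <- smallSimConfig(seed = 37L, effectSpec = c(1, 0.7, 1))
  gt <- makeGroundTruth(cfg)
  W <- synthTensor5D(gt, cfg)
  master <- masterDecomposition(W, decomposeConfig(rank = 3, seed = 6,
                                                   nRestarts = 2))
  alphaIdx <- congruence(master, groundTruthModel(gt), modes = 1:3)$matching[2]
  pt <- permutationTest(W, master, contrastModel(2), nPerm = 200, seed = 3)
  tab <- resultTable(pt)
  lev <- tab[tab$contrast == "post-LEV - pre-LEV", ]
  expect_true(lev$decision[lev$component == alphaIdx])
  expect_lt(lev$observed[lev$component == alphaIdx], 0)
})
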