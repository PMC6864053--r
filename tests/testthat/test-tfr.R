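test_that("evoked subtraction centres trials and preserves induced band power", {
  ep <- noiseEpochs(nTrials = 4L, seed = 1L)
  out <- subtractEvoked(ep)
  sums <- colSums(tensorValues(out))          # channels x samples
  expect_lt(max(abs(sums)), 1e-10)
  # identical trials cancel completely
  x <- tensorValues(ep)
  for (i in seq_len(dim(x)[1])) x[i, , ] <- x[1, , ]
  expect_lt(max(abs(tensorValues(subtractEvoked(initialize(ep, data = x))))),
            1e-12)
  expect_error(subtractEvoked(epochSet(array(1, c(1, 2, 100)))), ">= 2")

  # phase-randomised oscillation: band power survives the subtraction
  gt <- alphaOnlyGroundTruth(seed = 5L, nChannels = 2L)
  ep2 <- synthEpochs(gt, nTrials = 30, seed = 6, noiseSd = 0.01)
  cfg <- tfrConfig(freqMin = 8, freqMax = 12)
  bandPower <- function(e) {
    P <- tensorValues(hanningTFR(e, cfg))
    mean(P[, , 3, ], na.rm = TRUE)            # the 10 Hz row
  }
  before <- bandPower(ep2)
  after <- bandPower(subtractEvoked(ep2))
  expect_gt(after / before, 0.95)
  expect_lt(after / before, 1.05)
})

test_that("hanning TFR produces the configured grid with flagged edges", {
  ep <- noiseEpochs(nTrials = 2L, nChannels = 1L, seed = 2L)
  tt <- hanningTFR(ep, tfrConfig())
  d <- dim(tensorValues(tt))
  expect_identical(d[3:4], c(42L, 201L))      # 4..45 Hz x -1000..1000 ms
  expect_equal(range(tt@times), c(-1000, 1000))
  # 10 Hz window spans 3.5 cycles = 0.35 s
  expect_identical(taperLength(1000, 3.5, 10), 351)
  # edge bins whose window exceeds the epoch are NA, never zero
  row4 <- tensorValues(tt)[1, 1, 1, ]          # 4 Hz: half-window 437 ms
  expect_true(all(is.na(row4[abs(tt@times) > 563])))
  expect_true(all(is.finite(row4[abs(tt@times) <= 563])))
  # a frequency whose window exceeds the whole epoch is fully flagged
  ttLow <- hanningTFR(ep, tfrConfig(freqMin = 1, freqMax = 4))
  expect_true(all(is.na(tensorValues(ttLow)[, , 1, ])))
})

test_that("a pure sinusoid peaks at its own frequency bin", {
  tm <- seq(-1, 1, by = 1e-3)
  x <- array(0, c(2, 1, length(tm)))
  x[1, 1, ] <- sin(2 * pi * 20 * tm)
  x[2, 1, ] <- sin(2 * pi * 20 * tm + 1.2)
  tt <- hanningTFR(epochSet(x, tmin = -1), tfrConfig())
  P <- tensorValues(tt)[1, 1, , ]
  interior <- which(colSums(is.na(P)) == 0)
  expect_true(length(interior) > 50)
  expect_true(all(tt@freqs[apply(P[, interior], 2, which.max)] == 20))
})

test_that("Hann-windowed power of a sinusoid concentrates near its frequency", {
  # direct single-window computation: >= 90% of the Parseval total lies
  # within +-1 DFT bin of the tone
  fs <- 1000; f0 <- 20
  L <- taperLength(fs, 3.5, f0)
  n <- seq(0, L - 1)
  h <- 0.5 * (1 - cos(2 * pi * n / (L - 1)))
  x <- sin(2 * pi * f0 * n / fs) * h
  X2 <- Mod(fft(x))^2
  freqsDft <- (n) * fs / L
  near <- abs(freqsDft - f0) <= fs / L | abs(freqsDft - (fs - f0)) <= fs / L
  expect_gte(sum(X2[near]) / sum(X2), 0.9)
})

test_that("z-transform gives unit moments per frequency and rejects degenerate rows", {
  ep <- noiseEpochs(nTrials = 3L, seed = 3L)
  tt <- hanningTFR(ep, tfrConfig())
  z <- znormTrials(tt)
  d <- dim(tensorValues(z))
  Xm <- matrix(tensorValues(z), prod(d[1:3]), d[4])
  expect_lt(max(abs(rowMeans(Xm, na.rm = TRUE))), 1e-10)
  sds <- apply(Xm, 1, sd, na.rm = TRUE)
  expect_lt(max(abs(sds - 1)), 1e-10)
  expect_identical(z@stage, "znorm")

  # scaling a trial leaves its z-transform unchanged
  ep5 <- initialize(ep, data = tensorValues(ep) * 5)
  z5 <- znormTrials(hanningTFR(ep5, tfrConfig()))
  expect_equal(tensorValues(z5), tensorValues(z), tolerance = 1e-9)

  # constant-power row errors with a named location
  bad <- tt
  bad@power[1, 1, 5, ] <- 2
  expect_error(znormTrials(bad), "zero temporal SD")
})

test_that("baseline correction zeroes the pre-stimulus window and is idempotent", {
  cfg <- tfrConfig()
  z <- znormTrials(hanningTFR(noiseEpochs(nTrials = 3L, seed = 4L), cfg))
  b <- baselineCorrect(z, cfg)
  sel <- b@times >= -100 & b@times <= -50
  base <- apply(tensorValues(b)[, , , sel, drop = FALSE], 1:3, mean)
  expect_lt(max(abs(base)), 1e-10)
  expect_equal(tensorValues(baselineCorrect(b, cfg)), tensorValues(b),
               tolerance = 1e-12)
  # shifting one frequency row by a constant changes nothing post-correction
  shifted <- z
  shifted@power[, , 2, ] <- shifted@power[, , 2, ] + 3.7
  expect_equal(tensorValues(baselineCorrect(shifted, cfg)), tensorValues(b),
               tolerance = 1e-10)
  expect_error(baselineCorrect(z, tfrConfig(baselineWindow = c(-107, -103))),
               "no time bins", fixed = FALSE)
})

test_that("averaging and cropping produce the expected axes", {
  cfg <- tfrConfig()
  z <- baselineCorrect(znormTrials(hanningTFR(noiseEpochs(nTrials = 2L, seed = 5L),
                                              cfg)), cfg)
  tt <- averageAndCrop(z, cfg)
  expect_identical(length(tt@freqs), 31L)     # 4..34 Hz from the 42-bin grid
  expect_identical(length(tt@times), 97L)     # 40..1000 ms on the 10 ms grid
  expect_identical(tt@nTrials, 2L)
  expect_identical(tt@nUndefined, sum(is.na(tensorValues(tt))))

  # identity crop = pure trial average
  full <- averageAndCrop(z, tfrConfig(cropTime = c(-1000, 1000),
                                      cropFreq = c(4, 45)))
  expect_equal(tensorValues(full),
               apply(tensorValues(z), 2:4, mean), tolerance = 1e-12)

  # two identical trials average to either trial
  x <- tensorValues(z)
  x[2, , , ] <- x[1, , , ]
  same <- averageAndCrop(initialize(z, power = x), cfg)
  expect_equal(tensorValues(same), x[1, , 1:31, z@times >= 40],
               tolerance = 1e-12)

  expect_error(averageAndCrop(z, tfrConfig(cropFreq = c(60, 70))),
               "excludes all bins")
  trimmed <- averageAndCrop(z, cfg, undefined = "trim")
  expect_identical(trimmed@nUndefined, 0L)
  expect_error(averageAndCrop(z, cfg, undefined = "error"), "undefined")
})

test_that("the one-call chain recovers the generating carrier frequency", {
  gt <- alphaOnlyGroundTruth(seed = 2L)
  ep <- synthEpochs(gt, nTrials = 12, seed = 3)
  tt <- tfrPipeline(ep, tfrConfig(), undefined = "trim")
  v <- tensorValues(tt)
  v[v < 0] <- 0
  m1 <- nncpALS(v, decomposeConfig(rank = 1, seed = 1, nRestarts = 2))
  peak <- tt@freqs[which.max(factorMatrices(m1)[[2]])]
  expect_lte(abs(peak - 10), 1)
})
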