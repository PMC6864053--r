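# Small reusable fixtures, all generated in code.

# Study-structured but desk-sized configuration.
smallSimConfig <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(nChannels = 8L, nFreqs = 6L, nTimes = 10L, nSubjects = 6L,
                   seed = seed)
  do.call(simConfig, utils::modifyList(defaults, args))
}

# Exact known-rank tensor with generic non-negative full-column-rank factors.
genericCPTensor <- function(dims, rank, seed = 1L, noiseSigma = 0) {
  set.seed(seed)
  U <- lapply(dims, function(d) abs(matrix(rnorm(d * rank), d, rank)) + 0.05)
  list(U = U, W = makeCPTensor(U, noiseSigma = noiseSigma, seed = seed + 1L))
}

# Rank-1 ground truth with a 10 Hz occipital component (single-carrier
# fixture for the time-frequency chain).
alphaOnlyGroundTruth <- function(seed = 2L, nChannels = 6L) {
  tpl <- list(space = "Oz", spaceSigma = 2,
              band = list(alpha = c(6, 13)), peakHz = 10,
              phases = list(beta = list(riseOn = 40, peak = 200, off = 500,
                                        reboundOn = 700, reboundFull = 900,
                                        reboundLevel = 0.3)))
  cfg <- simConfig(nChannels = nChannels, nFreqs = 31L, nTimes = 98L,
                   nSubjects = 3L, rank = 1L, seed = seed, templates = tpl,
                   effectSpec = 1)
  makeGroundTruth(cfg)
}

# Tiny epoch set of pure noise on the full -1..+1 s grid.
noiseEpochs <- function(nTrials = 3L, nChannels = 2L, seed = 1L) {
  set.seed(seed)
  epochSet(array(rnorm(nTrials * nChannels * 2001), c(nTrials, nChannels, 2001)),
           tmin = -1)
}

expect_monotone_trace <- function(model) {
  tr <- attr(model, "objTrace")
  expect_true(length(tr) >= 1L)
  if (length(tr) > 1L)
    expect_true(all(diff(tr) <= 1e-8 * max(tr[1], 1)))
}
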