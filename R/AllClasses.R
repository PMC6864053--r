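#' @import methods
#' @importFrom stats rnorm runif quantile approx sd
NULL

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Dimensions, axes and component templates for the synthetic TMS-EEG
#' generator.  Defaults reproduce the study-shaped tensor: 61 channels on a
#' 10-10-like montage, a 4--34 Hz frequency axis (31 bins), a 40--1010 ms time
#' axis (98 bins, 10 ms steps), 13 subjects and 4 pre/post drug conditions,
#' with three ground-truth components (frontal--central beta, occipital alpha,
#' theta at the stimulated electrode C3).
#'
#' @slot nChannels number of EEG channels (subset of the packaged montage).
#' @slot nFreqs number of frequency bins spanning \code{freqRange}.
#' @slot nTimes number of time bins spanning \code{timeRange} (ms).
#' @slot nSubjects number of subjects.
#' @slot nConditions number of conditions (labels in \code{conditionLabels}).
#' @slot rank number of ground-truth components.
#' @slot seed integer seed; every stochastic draw derives from it.
#' @slot freqRange,timeRange axis end points (Hz, ms post-pulse).
#' @slot noiseSigma additive tensor noise SD, as a fraction of the noiseless
#'   signal root-mean-square.
#' @slot subjectSpread SD of the |Normal(1, spread^2)| subject loadings.
#' @slot noiseFamily "gaussian" (default) or "t" (df 4, heavier tails).
#' @slot conditionLabels ordered condition labels.
#' @slot effectSpec per-component multiplicative factor applied to post-drug
#'   (non-placebo) condition rows of the condition loadings.
#' @slot templates list with spatial centre channels, spectral band edges and
#'   carrier peaks, and temporal phase boundaries of the three components.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nChannels = "integer", nFreqs = "integer", nTimes = "integer",
  nSubjects = "integer", nConditions = "integer", rank = "integer",
  seed = "integer", freqRange = "numeric", timeRange = "numeric",
  noiseSigma = "numeric", subjectSpread = "numeric", noiseFamily = "character",
  conditionLabels = "character", effectSpec = "numeric", templates = "list"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  cnt <- c(object@nChannels, object@nFreqs, object@nTimes, object@nSubjects,
           object@nConditions, object@rank)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (object@rank > min(object@nChannels, object@nFreqs, object@nTimes,
                        object@nSubjects, object@nConditions))
    msg <- c(msg, "rank must not exceed the smallest mode size")
  if (length(object@conditionLabels) != object@nConditions)
    msg <- c(msg, "conditionLabels length must equal nConditions")
  if (anyDuplicated(object@conditionLabels))
    msg <- c(msg, "conditionLabels must be distinct")
  if (length(object@effectSpec) != object@rank)
    msg <- c(msg, "effectSpec must have one entry per component")
  if (any(object@effectSpec < 0)) msg <- c(msg, "effectSpec must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (!object@noiseFamily %in% c("gaussian", "t"))
    msg <- c(msg, "noiseFamily must be 'gaussian' or 't'")
  if (length(msg)) msg else TRUE
})

#' Time-frequency analysis configuration
#'
#' Parameters of the Hanning-taper windowed FFT and the normalisation chain.
#' Defaults: 3.5 cycles per window, 10 ms time steps, 1 Hz frequency steps
#' from 4 to 45 Hz, z-scores over the full trial length, absolute baseline
#' correction over -100..-50 ms, and a final crop to 40 ms..end and 4--34 Hz.
#'
#' @slot cyclesPerWindow taper length in cycles of the analysed frequency.
#' @slot timeStep output time-grid step (ms).
#' @slot freqMin,freqMax,freqStep output frequency grid (Hz).
#' @slot baselineWindow two-element window (ms, pre-stimulus) whose mean is
#'   subtracted per frequency.
#' @slot cropTime,cropFreq inclusive crop windows (ms / Hz) applied after
#'   trial averaging.
#' @slot zscorePower if TRUE (default) power (squared magnitude) is z-scored;
#'   if FALSE, amplitude.
#' @exportClass TFRConfig
setClass("TFRConfig", representation(
  cyclesPerWindow = "numeric", timeStep = "numeric",
  freqMin = "numeric", freqMax = "numeric", freqStep = "numeric",
  baselineWindow = "numeric", cropTime = "numeric", cropFreq = "numeric",
  zscorePower = "logical"))

setValidity("TFRConfig", function(object) {
  msg <- character(0)
  if (object@freqMin < 1) msg <- c(msg, "freqMin must be >= 1 Hz")
  if (object@freqMax < object@freqMin) msg <- c(msg, "freqMax < freqMin")
  if (object@freqStep <= 0 || object@timeStep <= 0)
    msg <- c(msg, "steps must be positive")
  if (object@cyclesPerWindow <= 0) msg <- c(msg, "cyclesPerWindow must be > 0")
  if (length(object@baselineWindow) != 2L ||
      diff(object@baselineWindow) <= 0 || object@baselineWindow[2] > 0)
    msg <- c(msg, "baselineWindow must be an increasing pre-stimulus (<= 0 ms) pair")
  if (length(object@cropTime) != 2L || diff(object@cropTime) <= 0)
    msg <- c(msg, "cropTime must be an increasing pair")
  if (length(object@cropFreq) != 2L || diff(object@cropFreq) <= 0)
    msg <- c(msg, "cropFreq must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' Decomposition configuration
#'
#' Settings of the alternating non-negative least-squares CP fit.
#'
#' @slot rank number of components.
#' @slot maxIterations maximum ALS sweeps (default 500).
#' @slot tol relative-fit convergence tolerance (default 1e-8).
#' @slot nRestarts random restarts, best fit kept (default 4).
#' @slot seed integer seed for the random initialisations.
#' @slot fixedModes integer mode indices never updated.
#' @slot init "random" or a list of initial factor matrices.
#' @slot nonneg impose the non-negativity constraint (default TRUE).
#' @exportClass DecomposeConfig
setClass("DecomposeConfig", representation(
  rank = "integer", maxIterations = "integer", tol = "numeric",
  nRestarts = "integer", seed = "integer", fixedModes = "integer",
  init = "ANY", nonneg = "logical"))

setValidity("DecomposeConfig", function(object) {
  msg <- character(0)
  if (object@rank < 1L) msg <- c(msg, "rank must be >= 1")
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (object@nRestarts < 1L) msg <- c(msg, "nRestarts must be >= 1")
  if (!(identical(object@init, "random") || is.list(object@init)))
    msg <- c(msg, "init must be 'random' or a list of matrices")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Ground-truth factor set of the synthetic generator
#'
#' Houses the per-mode profiles of the simulated components: spatial,
#' spectral and temporal factor matrices plus subject and condition loadings.
#' The first four matrices have non-negative, unit-Euclidean-norm columns;
#' all component scale lives in the condition loadings.  \code{effectSpec}
#' holds the per-component multiplicative factor applied to post-drug
#' condition rows when a tensor is synthesised.
#'
#' @slot spaceFactors channels x R matrix.
#' @slot freqFactors freqs x R matrix.
#' @slot timeFactors times x R matrix.
#' @slot subjectLoadings subjects x R matrix.
#' @slot conditionLoadings conditions x R base loadings (pre-effect).
#' @slot conditionLabels ordered condition labels.
#' @slot effectSpec numeric vector, one multiplicative factor per component.
#' @slot noiseSigma additive noise SD as a fraction of signal RMS.
#' @slot channels,freqs,times axis labels (channel names, Hz, ms).
#' @slot metadata list; \code{extraComponents} flags components beyond the
#'   three named templates (drawn as random smooth profiles).
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  spaceFactors = "matrix", freqFactors = "matrix", timeFactors = "matrix",
  subjectLoadings = "matrix", conditionLoadings = "matrix",
  conditionLabels = "character", effectSpec = "numeric",
  noiseSigma = "numeric", channels = "character", freqs = "numeric",
  times = "numeric", metadata = "list"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  mats <- list(object@spaceFactors, object@freqFactors, object@timeFactors,
               object@subjectLoadings, object@conditionLoadings)
  R <- ncol(object@spaceFactors)
  if (any(vapply(mats, function(m) any(m < 0), logical(1))))
    msg <- c(msg, "all factor entries must be >= 0")
  if (any(vapply(mats, ncol, integer(1)) != R))
    msg <- c(msg, "all factor matrices must have the same number of columns")
  for (m in mats[1:4]) {
    nrm <- sqrt(colSums(m^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "columns of the first four factor matrices must have unit norm")
  }
  if (length(object@conditionLabels) != nrow(object@conditionLoadings))
    msg <- c(msg, "conditionLabels length must equal conditionLoadings rows")
  if (length(object@effectSpec) != R)
    msg <- c(msg, "effectSpec must have one entry per component")
  if (length(msg)) msg else TRUE
})

#' Per-trial multichannel EEG epochs
#'
#' Raw input of the time-frequency chain: trials x channels x samples, in
#' microvolts, sampled uniformly around the stimulation pulse.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot samplingRate sampling rate (Hz).
#' @slot times sample times (s) relative to the pulse, strictly increasing
#'   with uniform step 1/samplingRate.
#' @slot channels channel labels.
#' @exportClass EpochSet
setClass("EpochSet", representation(
  data = "array", samplingRate = "numeric", times = "numeric",
  channels = "character"))

setValidity("EpochSet", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be trials x channels x samples")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "channel labels must match data dim 2")
    if (d[3] != length(object@times))
      msg <- c(msg, "time axis must match data dim 3")
  }
  dt <- diff(object@times)
  if (any(dt <= 0)) msg <- c(msg, "time axis must be strictly increasing")
  if (max(abs(dt - 1 / object@samplingRate)) > 1e-9)
    msg <- c(msg, "time axis step must equal 1/samplingRate")
  if (length(msg)) msg else TRUE
})

#' Single-trial time-frequency power
#'
#' Power of every trial, channel, frequency and output time bin.  Bins whose
#' analysis window does not fit inside the epoch are flagged undefined (NA),
#' never zero-padded.
#'
#' @slot power numeric array, trials x channels x freqs x times; NA = flagged.
#' @slot channels channel labels.
#' @slot freqs frequency axis (Hz).
#' @slot times output time axis (ms relative to the pulse).
#' @slot stage last applied stage ("power", "znorm" or "baseline").
#' @exportClass TrialTFR
setClass("TrialTFR", representation(
  power = "array", channels = "character", freqs = "numeric",
  times = "numeric", stage = "character"))

setValidity("TrialTFR", function(object) {
  d <- dim(object@power)
  if (length(d) != 4L) return("power must be trials x channels x freqs x times")
  if (d[2] != length(object@channels)) return("channel labels mismatch")
  if (d[3] != length(object@freqs)) return("frequency axis mismatch")
  if (d[4] != length(object@times)) return("time axis mismatch")
  TRUE
})

#' One subject/condition induced-power tensor
#'
#' Trial-averaged, baseline-corrected z-scored power on the cropped
#' channel x frequency x time grid, with provenance.
#'
#' @slot values numeric array, channels x freqs x times (z-units).
#' @slot channels,freqs,times axis labels (names, Hz, ms).
#' @slot subject,condition provenance identifiers.
#' @slot nTrials number of trials averaged.
#' @slot nUndefined number of flagged-undefined bins retained in the crop.
#' @exportClass TFRTensor
setClass("TFRTensor", representation(
  values = "array", channels = "character", freqs = "numeric",
  times = "numeric", subject = "character", condition = "character",
  nTrials = "integer", nUndefined = "integer"))

setValidity("TFRTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be channels x freqs x times")
  if (d[1] != length(object@channels)) return("channel labels mismatch")
  if (d[2] != length(object@freqs)) return("frequency axis mismatch")
  if (d[3] != length(object@times)) return("time axis mismatch")
  nNA <- sum(!is.finite(object@values))
  if (nNA != object@nUndefined)
    return("nUndefined must record the number of non-finite entries")
  TRUE
})

#' Five-way analysis tensor
#'
#' Stacked space x frequency x time x subject x condition array with labelled
#' axes; the input of the master decomposition and the permutation test.
#'
#' @slot values numeric 5-way array.
#' @slot channels,freqs,times,subjects,conditionLabels axis labels.
#' @exportClass Tensor5D
setClass("Tensor5D", representation(
  values = "array", channels = "character", freqs = "numeric",
  times = "numeric", subjects = "character", conditionLabels = "character"))

setValidity("Tensor5D", function(object) {
  d <- dim(object@values)
  if (length(d) != 5L) return("values must be a 5-way array")
  lab <- c(length(object@channels), length(object@freqs),
           length(object@times), length(object@subjects),
           length(object@conditionLabels))
  if (!all(d == lab)) return("mode sizes must match label lengths")
  if (any(!is.finite(object@values))) return("entries must be finite")
  TRUE
})

#' Canonical polyadic (PARAFAC) model
#'
#' One factor matrix per mode (columns = components) plus fit diagnostics.
#' Under the canonical normalisation all modes except the last carry
#' unit-norm columns and the component scale lives in the last mode.
#'
#' @slot factors list of non-negative factor matrices, one per mode.
#' @slot rank number of components.
#' @slot fitPercent explained variance of the fit (percent).
#' @slot iterations ALS sweeps used by the winning restart.
#' @slot converged logical convergence flag.
#' @slot normalization "raw" or "canonical".
#' @slot modeNames names of the modes.
#' @exportClass CPModel
setClass("CPModel", representation(
  factors = "list", rank = "integer", fitPercent = "numeric",
  iterations = "integer", converged = "logical", normalization = "character",
  modeNames = "character"))

setValidity("CPModel", function(object) {
  msg <- character(0)
  if (!all(vapply(object@factors, is.matrix, logical(1))))
    msg <- c(msg, "factors must be matrices")
  ranks <- vapply(object@factors, ncol, integer(1))
  if (any(ranks != object@rank))
    msg <- c(msg, "all factor matrices must have 'rank' columns")
  if (length(object@fitPercent) == 1 && is.finite(object@fitPercent) &&
      object@fitPercent > 100 + 1e-8)
    msg <- c(msg, "fitPercent must be <= 100")
  if (!object@normalization %in% c("raw", "canonical"))
    msg <- c(msg, "normalization must be 'raw' or 'canonical'")
  if (length(msg)) msg else TRUE
})

#' Contrast specification for the drug-effect models
#'
#' Which four conditions populate the 5th tensor mode and which
#' (post, pre) loading differences are tested.
#'
#' @slot modelId integer 1--4.
#' @slot conditionLabels ordered labels of the condition mode.
#' @slot contrasts list of c(post, pre) label pairs.
#' @slot betweenDrug optional list of two c(post, pre) pairs whose
#'   difference-of-differences is tested; empty list if none.
#' @exportClass ContrastModel
setClass("ContrastModel", representation(
  modelId = "integer", conditionLabels = "character",
  contrasts = "list", betweenDrug = "list"))

setValidity("ContrastModel", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@conditionLabels))
    msg <- c(msg, "condition labels must be distinct")
  labs <- unlist(c(object@contrasts, object@betweenDrug))
  if (!all(labs %in% object@conditionLabels))
    msg <- c(msg, "every contrast label must be a condition label")
  bad <- vapply(object@contrasts, function(p) length(p) != 2L, logical(1))
  if (any(bad)) msg <- c(msg, "each contrast must be a (post, pre) pair")
  if (length(object@betweenDrug) && length(object@betweenDrug) != 2L)
    msg <- c(msg, "betweenDrug must hold exactly two (post, pre) pairs")
  if (length(msg)) msg else TRUE
})

#' Permutation-test result
#'
#' Observed condition-loading differences, permutation null samples,
#' two-tailed p-values and per-tail 2.5\% decisions, per component and
#' contrast.
#'
#' @slot table data.frame: component, contrast, observed, p, decision.
#' @slot null matrix nPerm x nStatistics of null differences.
#' @slot nPerm number of permutations.
#' @slot seed seed used.
#' @slot scheme permutation scheme ("within_subject" or "joint").
#' @exportClass PermutationResult
setClass("PermutationResult", representation(
  table = "data.frame", null = "matrix", nPerm = "integer",
  seed = "integer", scheme = "character"))

setValidity("PermutationResult", function(object) {
  msg <- character(0)
  if (nrow(object@null) != object@nPerm)
    msg <- c(msg, "null sample length must equal nPerm")
  if (ncol(object@null) != nrow(object@table))
    msg <- c(msg, "one null column per tested statistic")
  p <- object@table$p
  if (any(p <= 0 | p > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
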