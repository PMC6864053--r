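## User-facing constructors with study defaults.

#' Default condition label sets
#'
#' Ordered condition labels of the four contrast models and of the full
#' six-condition rank-selection tensor.
#'
#' @param modelId 1--4, or "all6" for the six-condition set.
#' @return character vector of condition labels.
#' @export
conditionSet <- function(modelId) {
  if (identical(modelId, "all6"))
    return(c("pre-placebo", "post-placebo", "pre-LEV", "post-LEV",
             "pre-LTG", "post-LTG"))
  switch(as.character(modelId),
    "1" = c("pre-placebo", "post-placebo", "pre-LEV", "pre-LTG"),
    "2" = c("pre-LEV", "post-LEV", "pre-LTG", "post-LTG"),
    "3" = c("pre-placebo", "post-placebo", "pre-LEV", "post-LEV"),
    "4" = c("pre-placebo", "post-placebo", "pre-LTG", "post-LTG"),
    stop("modelId must be 1, 2, 3, 4 or 'all6'"))
}

#' Create a simulation configuration
#'
#' @param nChannels,nFreqs,nTimes,nSubjects,nConditions mode sizes; defaults
#'   are the study shape 61 x 31 x 98 x 13 x 4.
#' @param rank number of ground-truth components (default 3).
#' @param seed integer seed.
#' @param freqRange frequency axis end points in Hz (default 4--34).
#' @param timeRange time axis end points in ms (default 40--1010, so the
#'   default 98 bins step by 10 ms).
#' @param noiseSigma additive noise SD as a fraction of signal RMS
#'   (default 0.05).
#' @param subjectSpread SD of the |Normal(1, spread^2)| subject loadings
#'   (default 0.2).
#' @param noiseFamily "gaussian" (default) or "t" for heavier tails.
#' @param conditionLabels ordered labels; defaults to the model-2 set for 4
#'   conditions, the full six-condition set for 6.
#' @param effectSpec per-component multiplicative factor applied to post-drug
#'   conditions; default c(1, 0.7, 1, ...): the drug reduces the
#'   occipital-alpha component by 30 percent.
#' @param templates list of component templates (centre channels, spectral
#'   bands and peaks, temporal phase boundaries in ms).
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nChannels = 8, nFreqs = 6, nTimes = 10,
#'                  nSubjects = 6, seed = 1)
#' @export
simConfig <- function(nChannels = 61L, nFreqs = 31L, nTimes = 98L,
                      nSubjects = 13L, nConditions = 4L, rank = 3L,
                      seed = 1L, freqRange = c(4, 34), timeRange = c(40, 1010),
                      noiseSigma = 0.05, subjectSpread = 0.2,
                      noiseFamily = "gaussian", conditionLabels = NULL,
                      effectSpec = NULL, templates = NULL) {
  if (is.null(conditionLabels)) {
    conditionLabels <- if (nConditions == 4L) conditionSet(2)
      else if (nConditions == 6L) conditionSet("all6")
      else paste0("cond", seq_len(nConditions))
  }
  if (is.null(effectSpec)) {
    effectSpec <- rep(1, rank)
    if (rank >= 2L) effectSpec[2L] <- 0.7
  }
  if (is.null(templates)) templates <- defaultTemplates()
  new("SimConfig",
      nChannels = as.integer(nChannels), nFreqs = as.integer(nFreqs),
      nTimes = as.integer(nTimes), nSubjects = as.integer(nSubjects),
      nConditions = as.integer(nConditions), rank = as.integer(rank),
      seed = as.integer(seed), freqRange = as.numeric(freqRange),
      timeRange = as.numeric(timeRange), noiseSigma = noiseSigma,
      subjectSpread = subjectSpread, noiseFamily = noiseFamily,
      conditionLabels = conditionLabels, effectSpec = effectSpec,
      templates = templates)
}

defaultTemplates <- function() {
  list(
    ## frontal-central beta: early peak, suppression, late rebound (ERD/ERS)
    space = c("FCz", "Oz", "C3"),
    spaceSigma = 2.0,
    band = list(beta = c(15, 30), alpha = c(6, 13), theta = c(4, 6)),
    peakHz = c(19, 10, 5),
    phases = list(
      beta  = list(riseOn = 40,  peak = 90,  off = 190,
                   reboundOn = 440, reboundFull = 600, reboundLevel = 0.7),
      alpha = list(onset = 140, plateau = 340),
      theta = list(riseOn = 40, peak = 90, hold = 240, off = 440)))
}

#' Create a time-frequency configuration
#'
#' Defaults are the reference analysis: Hanning taper of 3.5 cycles, 10 ms
#' steps, 1 Hz bins from 4 to 45 Hz, z-transform over the full trial length,
#' baseline -100..-50 ms, crop to 40 ms..end and 4--34 Hz.
#'
#' @param cyclesPerWindow,timeStep,freqMin,freqMax,freqStep see
#'   \linkS4class{TFRConfig}.
#' @param baselineWindow,cropTime,cropFreq windows in ms / Hz.
#' @param zscorePower z-score power (TRUE, default) or amplitude.
#' @return a validated \linkS4class{TFRConfig}.
#' @export
tfrConfig <- function(cyclesPerWindow = 3.5, timeStep = 10,
                      freqMin = 4, freqMax = 45, freqStep = 1,
                      baselineWindow = c(-100, -50),
                      cropTime = c(40, 1000), cropFreq = c(4, 34),
                      zscorePower = TRUE) {
  new("TFRConfig", cyclesPerWindow = cyclesPerWindow, timeStep = timeStep,
      freqMin = freqMin, freqMax = freqMax, freqStep = freqStep,
      baselineWindow = as.numeric(baselineWindow),
      cropTime = as.numeric(cropTime), cropFreq = as.numeric(cropFreq),
      zscorePower = zscorePower)
}

#' Create a decomposition configuration
#'
#' @param rank number of components.
#' @param maxIterations maximum ALS sweeps (default 500).
#' @param tol relative-fit convergence tolerance (default 1e-8).
#' @param nRestarts random restarts, best fit kept (default 4).
#' @param seed integer seed.
#' @param fixedModes integer mode indices never updated.
#' @param init "random" (|Normal| entries) or a list of starting matrices.
#' @param nonneg impose non-negativity (default TRUE).
#' @return a validated \linkS4class{DecomposeConfig}.
#' @export
decomposeConfig <- function(rank, maxIterations = 500L, tol = 1e-8,
                            nRestarts = 4L, seed = 1L,
                            fixedModes = integer(0), init = "random",
                            nonneg = TRUE) {
  new("DecomposeConfig", rank = as.integer(rank),
      maxIterations = as.integer(maxIterations), tol = tol,
      nRestarts = as.integer(nRestarts), seed = as.integer(seed),
      fixedModes = as.integer(fixedModes), init = init, nonneg = nonneg)
}

#' Create a contrast model
#'
#' Builds the condition set and tested contrasts of models 1--4: model 1 is
#' the no-drug proof of concept (pre/post placebo plus the two pre-drug
#' baselines), model 2 contrasts the two drugs, models 3 and 4 contrast each
#' drug against placebo.  Each (post, pre) pair is tested per component; in
#' model 2 the between-drug difference-of-differences is tested too.
#'
#' @param modelId integer 1--4.
#' @param conditionLabels optional custom labels replacing the defaults.
#' @return a validated \linkS4class{ContrastModel}.
#' @examples
#' contrastModel(2)
#' @export
contrastModel <- function(modelId, conditionLabels = NULL) {
  modelId <- as.integer(modelId)
  labs <- if (is.null(conditionLabels)) conditionSet(modelId)
          else as.character(conditionLabels)
  pairs <- switch(modelId,
    list(c("post-placebo", "pre-placebo")),
    list(c("post-LEV", "pre-LEV"), c("post-LTG", "pre-LTG")),
    list(c("post-placebo", "pre-placebo"), c("post-LEV", "pre-LEV")),
    list(c("post-placebo", "pre-placebo"), c("post-LTG", "pre-LTG")))
  if (!is.null(conditionLabels)) {
    ## map default pair positions onto the custom labels
    def <- conditionSet(modelId)
    pairs <- lapply(pairs, function(p) labs[match(p, def)])
  }
  between <- if (modelId == 2L) pairs[1:2]
    else if (modelId %in% c(3L, 4L)) pairs[2:1]  # drug minus placebo
    else list()
  new("ContrastModel", modelId = modelId, conditionLabels = labs,
      contrasts = pairs, betweenDrug = between)
}

#' Assemble an EpochSet
#'
#' @param data trials x channels x samples numeric array (microvolts).
#' @param samplingRate sampling rate in Hz.
#' @param times sample times in seconds relative to the pulse; derived from
#'   \code{tmin} when omitted.
#' @param channels channel labels.
#' @param tmin epoch start (s) used when \code{times} is NULL.
#' @return a validated \linkS4class{EpochSet}.
#' @export
epochSet <- function(data, samplingRate = 1000, times = NULL,
                     channels = NULL, tmin = -1) {
  d <- dim(data)
  if (is.null(times)) times <- tmin + (seq_len(d[3]) - 1) / samplingRate
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  new("EpochSet", data = data, samplingRate = samplingRate,
      times = times, channels = channels)
}

#' Assemble a five-way tensor
#'
#' @param values 5-way numeric array (space x frequency x time x subject x
#'   condition).
#' @param channels,freqs,times,subjects,conditionLabels axis labels; defaults
#'   are generated when omitted.
#' @return a validated \linkS4class{Tensor5D}.
#' @export
tensor5D <- function(values, channels = NULL, freqs = NULL, times = NULL,
                     subjects = NULL, conditionLabels = NULL) {
  d <- dim(values)
  stopifnot(length(d) == 5L)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[1]))
  if (is.null(freqs)) freqs <- seq_len(d[2])
  if (is.null(times)) times <- seq_len(d[3])
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_len(d[4]))
  if (is.null(conditionLabels)) conditionLabels <- paste0("cond", seq_len(d[5]))
  new("Tensor5D", values = values, channels = channels, freqs = freqs,
      times = times, subjects = subjects, conditionLabels = conditionLabels)
}
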