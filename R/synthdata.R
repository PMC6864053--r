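## Synthetic TMS-EEG generator: ground-truth factor sets, factor-structured
## five-way tensors with injectable drug effects, and raw epochs whose
## time-frequency transform approximates a given factor structure.

#' Read a channel montage
#'
#' Tab-delimited text with columns label/x/y, one row per channel.  The
#' packaged default is a 61-channel 10-10-like layout on a flattened head
#' (the stimulation site C3 and the template centres FCz and Oz included).
#'
#' @param path montage file; default: the packaged 61-channel layout.
#' @return data.frame with columns label, x, y.
#' @export
readMontage <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "montage61.tsv", package = "tensoreeg")
  mon <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y") %in% names(mon)))
  mon
}

## Deterministic channel subset that always keeps the template centres.
subsetMontage <- function(mon, nChannels, centres) {
  if (nChannels > nrow(mon))
    stop("montage has only ", nrow(mon), " channels")
  if (nChannels == nrow(mon)) return(mon)
  keep <- match(centres, mon$label)
  keep <- keep[!is.na(keep)]
  rest <- setdiff(seq_len(nrow(mon)), keep)
  extra <- rest[round(seq(1, length(rest), length.out = nChannels - length(keep)))]
  mon[sort(c(keep, extra)), , drop = FALSE]
}

## Smooth half-cosine ramp from 0 at a to 1 at b.
smoothstep <- function(t, a, b) {
  u <- pmin(pmax((t - a) / (b - a), 0), 1)
  0.5 * (1 - cos(pi * u))
}

## Smooth non-negative bump: rise over [on, peak], fall over [peak, off].
cosBump <- function(t, on, peak, off) {
  smoothstep(t, on, peak) * (1 - smoothstep(t, peak, off))
}

unitCols <- function(M) sweep(M, 2L, sqrt(colSums(M^2)), "/")

## Random smooth non-negative profile for components beyond the templates.
randomSmoothProfile <- function(axis) {
  centre <- runif(1, min(axis), max(axis))
  width <- diff(range(axis)) * runif(1, 0.1, 0.3)
  exp(-(axis - centre)^2 / (2 * width^2)) + 0.05
}

#' Generate a ground-truth factor set
#'
#' Builds the component profiles the generator embeds in the data: smooth
#' non-negative spatial bumps over 2-D montage coordinates centred on the
#' configured channels (frontal-central, occipital, stimulation site C3);
#' spectral bumps peaking inside the beta (15--30 Hz), alpha (6--13 Hz) and
#' theta (4--6 Hz) bands; temporal profiles following the beta
#' peak/suppression/rebound shape, the delayed alpha rise (onset about
#' 140 ms) and the early theta peak (about 90--240 ms) with later
#' suppression.  Subject loadings are drawn as |Normal(1, spread^2)|.
#' Components beyond the three templates are drawn as random smooth
#' non-negative profiles and flagged in the metadata.  Deterministic given
#' the configuration seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param montage optional montage data.frame (default: packaged layout).
#' @return a \linkS4class{GroundTruth}.
#' @examples
#' gt <- makeGroundTruth(simConfig(nChannels = 8, nFreqs = 8, nTimes = 12,
#'                                 nSubjects = 4, seed = 1))
#' @export
makeGroundTruth <- function(config, montage = NULL) {
  validObject(config)
  set.seed(config@seed)
  tpl <- config@templates
  mon <- if (is.null(montage)) readMontage() else montage
  mon <- subsetMontage(mon, config@nChannels, tpl$space)
  R <- config@rank

  freqs <- seq(config@freqRange[1], config@freqRange[2],
               length.out = config@nFreqs)
  times <- seq(config@timeRange[1], config@timeRange[2],
               length.out = config@nTimes)

  nTpl <- min(R, 3L)
  A <- matrix(0, nrow(mon), R)
  B <- matrix(0, length(freqs), R)
  C <- matrix(0, length(times), R)

  bands <- tpl$band
  for (r in seq_len(nTpl)) {
    centre <- mon[match(tpl$space[r], mon$label), c("x", "y")]
    if (anyNA(centre)) stop("centre channel ", tpl$space[r], " not in montage")
    d2 <- (mon$x - centre$x)^2 + (mon$y - centre$y)^2
    A[, r] <- exp(-d2 / (2 * tpl$spaceSigma^2))
    band <- bands[[r]]
    B[, r] <- exp(-(freqs - tpl$peakHz[r])^2 / (2 * (diff(band) / 4)^2))
  }
  if (nTpl >= 1L) {
    p <- tpl$phases$beta
    C[, 1] <- cosBump(times, p$riseOn, p$peak, p$off) +
      p$reboundLevel * smoothstep(times, p$reboundOn, p$reboundFull)
  }
  if (nTpl >= 2L) {
    p <- tpl$phases$alpha
    C[, 2] <- smoothstep(times, p$onset, p$plateau)
  }
  if (nTpl >= 3L) {
    p <- tpl$phases$theta
    C[, 3] <- smoothstep(times, p$riseOn, p$peak) *
      (1 - smoothstep(times, p$hold, p$off))
  }
  extra <- R > nTpl
  if (extra) for (r in (nTpl + 1L):R) {
    A[, r] <- randomSmoothProfile(rank(mon$x + 10 * mon$y))
    B[, r] <- randomSmoothProfile(freqs)
    C[, r] <- randomSmoothProfile(times)
  }

  D <- matrix(abs(rnorm(config@nSubjects * R, mean = 1,
                        sd = config@subjectSpread)), config@nSubjects, R)
  E <- matrix(1, config@nConditions, R)

  new("GroundTruth",
      spaceFactors = unitCols(A), freqFactors = unitCols(B),
      timeFactors = unitCols(C), subjectLoadings = unitCols(D),
      conditionLoadings = E, conditionLabels = config@conditionLabels,
      effectSpec = config@effectSpec, noiseSigma = config@noiseSigma,
      channels = mon$label, freqs = freqs, times = times,
      metadata = list(extraComponents = extra, montage = mon,
                      seed = config@seed))
}

#' Synthesise a five-way tensor from a ground truth
#'
#' Builds \code{W[i,j,k,s,c] = sum_r A[i,r] B[j,r] C[k,r] D[s,r] E'[c,r]}
#' plus additive noise, where E' is the condition-loading matrix with the
#' per-component multiplicative drug effect applied to post-drug rows.  The
#' noise SD equals \code{noiseSigma} times the noiseless signal RMS;
#' noiseFamily "t" replaces the Gaussian with a scaled t(4) for heavier
#' tails.  Deterministic given the configuration seed.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param config the \linkS4class{SimConfig} used to create it.
#' @return a \linkS4class{Tensor5D} with labelled axes.
#' @export
synthTensor5D <- function(gt, config) {
  U <- factorList(gt)
  sizes <- vapply(U, nrow, integer(1))
  want <- c(config@nChannels, config@nFreqs, config@nTimes,
            config@nSubjects, config@nConditions)
  if (!identical(as.integer(sizes), as.integer(want)))
    stop("factor shapes ", paste(sizes, collapse = "x"),
         " do not match config mode sizes ", paste(want, collapse = "x"))
  signal <- cpReconstruct(U)
  sigma <- gt@noiseSigma * sqrt(mean(signal^2))
  set.seed(config@seed + 1L)
  n <- length(signal)
  noise <- if (sigma == 0) 0
    else if (config@noiseFamily == "t")
      sigma * stats::rt(n, df = 4) / sqrt(2)  # t(4) variance is 2
    else rnorm(n, sd = sigma)
  values <- signal + array(noise, dim(signal))
  tensor5D(values, channels = gt@channels, freqs = gt@freqs,
           times = gt@times,
           subjects = sprintf("S%02d", seq_len(config@nSubjects)),
           conditionLabels = gt@conditionLabels)
}

#' Synthesise a tensor from explicit factor matrices
#'
#' Low-level generator: builds \code{sum_r} of the outer products of the
#' given factor columns plus optional Gaussian noise.  Useful for
#' constructing exact known-rank tensors with generic (full-column-rank)
#' loadings, e.g. for core-consistency diagnostics, where the pre/post drug
#' structure of \code{\link{synthTensor5D}} would make the condition
#' loadings rank-deficient by design.
#'
#' @param factors list of factor matrices, one per mode, equal column counts.
#' @param noiseSigma additive noise SD as a fraction of signal RMS.
#' @param seed integer seed for the noise.
#' @return a numeric array of order \code{length(factors)}.
#' @examples
#' U <- lapply(c(6, 5, 4), function(d) abs(matrix(rnorm(d * 2), d, 2)))
#' W <- makeCPTensor(U)  # exact rank-2
#' @export
makeCPTensor <- function(factors, noiseSigma = 0, seed = 1L) {
  stopifnot(is.list(factors), length(factors) >= 3L,
            length(unique(vapply(factors, ncol, integer(1)))) == 1L)
  signal <- cpReconstruct(factors)
  if (noiseSigma > 0) {
    set.seed(seed)
    signal <- signal + array(rnorm(length(signal),
                                   sd = noiseSigma * sqrt(mean(signal^2))),
                             dim(signal))
  }
  signal
}

#' Synthesise raw EEG epochs from a ground truth
#'
#' Each trial is, per channel, a sum over components of band-limited
#' oscillations: a carrier at the component's spectral peak with a random
#' per-trial phase (so the power is induced, not evoked), an envelope that
#' follows the component's temporal profile, and an amplitude scaled by the
#' spatial profile and the chosen subject's loading, plus broadband Gaussian
#' noise.  Sampling is 1 kHz over -1..+1 s around the pulse.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param nTrials number of trials (>= 2).
#' @param seed integer seed.
#' @param subject subject index whose loadings scale the components.
#' @param condition condition index selecting the (effect-applied) loading.
#' @param amplitude oscillation amplitude multiplier (microvolts per unit
#'   profile product; default 60 makes induced power dominate the unit
#'   broadband noise).
#' @param noiseSd broadband noise SD in microvolts (default 1).
#' @return an \linkS4class{EpochSet}.
#' @export
synthEpochs <- function(gt, nTrials, seed = 1L, subject = 1L,
                        condition = 1L, amplitude = 60, noiseSd = 1) {
  if (nTrials < 2L) stop("nTrials must be >= 2")
  set.seed(seed)
  fs <- 1000
  times <- seq(-1, 1, by = 1 / fs)
  nS <- length(times)
  nCh <- length(gt@channels)
  R <- ncol(gt@spaceFactors)
  Eapp <- appliedConditionLoadings(gt)
  carriers <- gt@freqs[apply(gt@freqFactors, 2L, which.max)]
  ## temporal envelopes interpolated onto the sample grid (profile times are
  ## ms post-pulse; zero outside the profile support)
  env <- vapply(seq_len(R), function(r) {
    e <- approx(gt@times / 1000, gt@timeFactors[, r], xout = times,
                yleft = 0, yright = 0, rule = 2)$y
    e[times < min(gt@times) / 1000 | times > max(gt@times) / 1000] <- 0
    e
  }, numeric(nS))
  data <- array(rnorm(nTrials * nCh * nS, sd = noiseSd),
                c(nTrials, nCh, nS))
  for (tr in seq_len(nTrials)) {
    phases <- runif(R, 0, 2 * pi)
    for (r in seq_len(R)) {
      carrier <- cos(2 * pi * carriers[r] * times + phases[r])
      amp <- amplitude * gt@spaceFactors[, r] *
        gt@subjectLoadings[subject, r] * Eapp[condition, r]
      data[tr, , ] <- data[tr, , ] + outer(amp, env[, r] * carrier)
    }
  }
  epochSet(data, samplingRate = fs, times = times, channels = gt@channels)
}
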