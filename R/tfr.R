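## Time-frequency chain: evoked subtraction, Hanning-taper windowed FFT with
## frequency-dependent window length, per-trial z-transform, absolute
## baseline correction, trial averaging and cropping.  The fixed order of
## the chain is enforced by tfrPipeline().

#' Subtract the evoked response from every trial
#'
#' Removes the phase-locked (evoked) component by subtracting the per-channel
#' time-domain trial average from each trial, isolating induced activity.
#'
#' @param epochs an \linkS4class{EpochSet} with at least two trials.
#' @return an \linkS4class{EpochSet}; trials now sum to zero at every
#'   channel and sample.
#' @export
subtractEvoked <- function(epochs) {
  x <- epochs@data
  if (dim(x)[1] < 2L)
    stop("evoked subtraction needs >= 2 trials (it would zero a single trial)")
  evoked <- colMeans(x)                   # channels x samples
  x <- x - rep(evoked, each = dim(x)[1])
  initialize(epochs, data = x)
}

## Odd taper length in samples for frequency f: round(fs * cycles / f).
taperLength <- function(fs, cycles, f) {
  L <- round(fs * cycles / f)
  L + (L %% 2L == 0L)
}

#' Hanning-taper windowed FFT
#'
#' Single-trial spectrogram with frequency-dependent window length: at each
#' frequency f the signal is tapered with a Hann window spanning
#' \code{cyclesPerWindow / f} seconds (odd sample count, centred on the
#' output bin) and projected on the complex exponential at f; power is the
#' squared magnitude.  The output grid is
#' \code{freqMin:freqStep:freqMax} by the epoch times at \code{timeStep}
#' spacing.  Bins whose window does not fit inside the epoch are flagged
#' undefined (NA), never zero-padded.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param cfg a \linkS4class{TFRConfig}.
#' @return a \linkS4class{TrialTFR} (stage "power").
#' @export
hanningTFR <- function(epochs, cfg) {
  x <- epochs@data
  d <- dim(x)
  fs <- epochs@samplingRate
  nS <- d[3]
  stepSamp <- round(cfg@timeStep / 1000 * fs)
  if (abs(stepSamp - cfg@timeStep / 1000 * fs) > 1e-9)
    stop("timeStep must be a multiple of the sampling interval")
  outIdx <- seq(1L, nS, by = stepSamp)
  outTimes <- epochs@times[outIdx] * 1000          # ms
  freqs <- seq(cfg@freqMin, cfg@freqMax, by = cfg@freqStep)
  power <- array(NA_real_, c(d[1], d[2], length(freqs), length(outIdx)))
  Xm <- matrix(x, d[1] * d[2], nS)                 # (trial,channel) x sample
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    L <- taperLength(fs, cfg@cyclesPerWindow, f)
    half <- (L - 1L) / 2L
    ok <- which(outIdx - half >= 1L & outIdx + half <= nS)
    if (!length(ok)) next                           # whole row stays flagged
    h <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
    h <- h / sum(h)   # coherent gain 1: a unit sinusoid at f reads amplitude
                      # 0.5 at every window length, so power is comparable
                      # across the frequency-dependent windows
    w <- h * exp(-2i * pi * f * (-half:half) / fs)
    Wmat <- matrix(0 + 0i, nS, length(ok))
    for (j in seq_along(ok))
      Wmat[(outIdx[ok[j]] - half):(outIdx[ok[j]] + half), j] <- w
    P <- Mod(Xm %*% Wmat)^2
    if (!cfg@zscorePower) P <- sqrt(P)
    power[, , fi, ok] <- array(P, c(d[1], d[2], length(ok)))
  }
  new("TrialTFR", power = power, channels = epochs@channels,
      freqs = freqs, times = outTimes, stage = "power")
}

#' Per-trial z-transform over the full trial length
#'
#' For every trial, channel and frequency, centres and scales the power time
#' course to mean 0 and SD 1, using the defined (non-flagged) time bins.
#'
#' @param tfr a \linkS4class{TrialTFR}.
#' @return a \linkS4class{TrialTFR} (stage "znorm").
#' @export
znormTrials <- function(tfr) {
  d <- dim(tfr@power)
  Xm <- matrix(tfr@power, prod(d[1:3]), d[4])
  nDef <- rowSums(!is.na(Xm))
  if (any(nDef < 2L)) {
    bad <- arrayInd(which(nDef < 2L)[1], d[1:3])
    stop(sprintf(
      "fewer than 2 defined time bins (trial %d, channel %d, frequency %g Hz)",
      bad[1], bad[2], tfr@freqs[bad[3]]))
  }
  mu <- rowMeans(Xm, na.rm = TRUE)
  sdv <- sqrt(rowSums((Xm - mu)^2, na.rm = TRUE) / (nDef - 1L))
  if (any(sdv == 0)) {
    bad <- arrayInd(which(sdv == 0)[1], d[1:3])
    stop(sprintf(
      "zero temporal SD (trial %d, channel %d, frequency %g Hz)",
      bad[1], bad[2], tfr@freqs[bad[3]]))
  }
  Xm <- (Xm - mu) / sdv
  initialize(tfr, power = array(Xm, d), stage = "znorm")
}

#' Absolute baseline correction
#'
#' Subtracts, per trial, channel and frequency, the mean over the
#' pre-stimulus baseline window so values represent change from the pre-TMS
#' baseline.
#'
#' @param tfr a \linkS4class{TrialTFR}.
#' @param cfg a \linkS4class{TFRConfig}; \code{baselineWindow} is the
#'   inclusive window in ms.
#' @return a \linkS4class{TrialTFR} (stage "baseline").
#' @export
baselineCorrect <- function(tfr, cfg) {
  sel <- tfr@times >= cfg@baselineWindow[1] & tfr@times <= cfg@baselineWindow[2]
  if (!any(sel)) stop("baseline window contains no time bins")
  d <- dim(tfr@power)
  Xm <- matrix(tfr@power, prod(d[1:3]), d[4])
  base <- rowMeans(Xm[, sel, drop = FALSE])
  if (anyNA(base)) {
    bad <- arrayInd(which(is.na(base))[1], d[1:3])
    stop(sprintf(
      "baseline window is flagged-undefined (trial %d, channel %d, frequency %g Hz)",
      bad[1], bad[2], tfr@freqs[bad[3]]))
  }
  initialize(tfr, power = array(Xm - base, d), stage = "baseline")
}

#' Average trials and crop the grid
#'
#' Averages out the trial dimension and restricts the axes to the configured
#' frequency and time crops.  Bins flagged undefined by the window geometry
#' remain undefined after averaging; \code{undefined} controls the policy:
#' "keep" retains them as NA (count recorded in the result), "trim"
#' additionally restricts the time axis to bins defined at every cropped
#' frequency, "error" refuses.
#'
#' @param tfr a \linkS4class{TrialTFR}.
#' @param cfg a \linkS4class{TFRConfig}.
#' @param subject,condition provenance identifiers.
#' @param undefined "keep" (default), "trim" or "error".
#' @return a \linkS4class{TFRTensor}.
#' @export
averageAndCrop <- function(tfr, cfg, subject = "S01", condition = "cond1",
                           undefined = c("keep", "trim", "error")) {
  undefined <- match.arg(undefined)
  fSel <- which(tfr@freqs >= cfg@cropFreq[1] & tfr@freqs <= cfg@cropFreq[2])
  tSel <- which(tfr@times >= cfg@cropTime[1] & tfr@times <= cfg@cropTime[2])
  if (!length(fSel) || !length(tSel))
    stop("crop window excludes all bins")
  d <- dim(tfr@power)
  avg <- colMeans(matrix(tfr@power, d[1], prod(d[2:4])))   # over trials
  avg <- array(avg, d[2:4])[, fSel, tSel, drop = FALSE]
  times <- tfr@times[tSel]
  if (undefined == "trim") {
    defined <- apply(!is.na(avg), 3L, all)
    avg <- avg[, , defined, drop = FALSE]
    times <- times[defined]
    if (!length(times)) stop("no fully defined time bins inside the crop")
  }
  nUndef <- sum(is.na(avg))
  if (undefined == "error" && nUndef > 0)
    stop(nUndef, " flagged-undefined bins inside the crop")
  new("TFRTensor", values = avg, channels = tfr@channels,
      freqs = tfr@freqs[fSel], times = times,
      subject = as.character(subject), condition = as.character(condition),
      nTrials = d[1], nUndefined = as.integer(nUndef))
}

#' Full induced-oscillation chain
#'
#' Enforces the fixed stage order: evoked subtraction, Hanning-taper
#' windowed FFT, per-trial z-transform, baseline correction, trial averaging
#' and cropping.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param cfg a \linkS4class{TFRConfig}.
#' @param subject,condition provenance identifiers.
#' @param undefined edge-bin policy, see \code{\link{averageAndCrop}}.
#' @return a \linkS4class{TFRTensor}.
#' @examples
#' gt <- makeGroundTruth(simConfig(nChannels = 4, nFreqs = 8, nTimes = 12,
#'                                 nSubjects = 2, seed = 3))
#' ep <- synthEpochs(gt, nTrials = 4, seed = 3)
#' tt <- tfrPipeline(ep, tfrConfig(freqMax = 20), undefined = "trim")
#' @export
tfrPipeline <- function(epochs, cfg = tfrConfig(), subject = "S01",
                        condition = "cond1", undefined = "keep") {
  out <- subtractEvoked(epochs)
  out <- hanningTFR(out, cfg)
  out <- znormTrials(out)
  out <- baselineCorrect(out, cfg)
  averageAndCrop(out, cfg, subject = subject, condition = condition,
                 undefined = undefined)
}
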