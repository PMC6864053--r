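---
title: "Methods: tensor decomposition of TMS-induced EEG oscillations"
author: "tensoreeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensor decomposition of TMS-induced EEG oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensoreeg)
```

## The problem

A transcranial magnetic stimulation (TMS) pulse perturbs the cortex and the
EEG response unfolds jointly over space (electrodes), frequency, time,
subjects and experimental conditions — for pharmaco-EEG, pre- and post-drug
sessions.  Conventional analyses pick windows and electrode sets a priori,
or lean on cluster-based permutation corrections; both struggle when several
conditions are tested at once.  `tensoreeg` instead treats the whole data
set as a single five-way tensor and extracts a small number of rank-one
components, each with one profile per mode, so a drug effect appears
directly as a change in a component's condition loading.

The package implements the full chain: single-trial time-frequency
transformation, tensorisation, non-negative canonical polyadic (CP/PARAFAC)
decomposition, rank selection, and permutation inference on condition
loadings, plus a synthetic-data generator with known ground truth used by
every test in the package.

## Induced-power maps (module `tfr`)

Input epochs are trials x channels x samples at 1 kHz, spanning -1..+1 s
around the pulse.  The chain is fixed, in this order
(`tfrPipeline()` enforces it):

1. **Evoked subtraction** (`subtractEvoked`): the per-channel trial average
   is removed from every trial, so only non-phase-locked (induced) power
   survives.
2. **Hanning-taper windowed FFT** (`hanningTFR`): at frequency $f$ the
   window spans $3.5/f$ seconds (frequency-dependent resolution), sampled
   on a 1 Hz x 10 ms output grid from 4 to 45 Hz.  On a -1..+1 s epoch
   this gives 42 frequency bins by 201 time bins.  Window lengths are
   rounded to an odd sample count so tapers are centred on their output
   bin.  The taper is normalised to unit coherent gain (`h/sum(h)`):
   a unit sinusoid reads the same amplitude at every window length, which
   keeps power comparable across frequencies before any normalisation.
3. **Per-trial z-transform** (`znormTrials`): each trial/channel/frequency
   time course is centred and scaled using moments over the full trial
   length (defined bins only, see below).
4. **Baseline correction** (`baselineCorrect`): the mean over the
   pre-stimulus -100..-50 ms window is subtracted per frequency, so values
   are changes from the pre-TMS baseline in z-units.
5. **Averaging and cropping** (`averageAndCrop`): trials are averaged and
   the grid is cropped to 40 ms..1 s and 4-34 Hz, away from residual pulse
   and DC-shift artefacts, giving one channels x 31 x times array per
   subject and condition.

**Edge handling.**  An output bin whose analysis window does not fit inside
the epoch is *flagged undefined* (NA), never zero-padded: zero-padding
would bias the z-transform.  A consequence worth stating plainly: on a
-1..+1 s epoch the 40..1000 ms crop contains flagged bins at *every*
frequency in 4-34 Hz (even at 34 Hz the window half-width is 51 ms, so
bins beyond 949 ms are undefined).  `averageAndCrop` therefore records the
flagged count in the result (`undefined = "keep"`), and offers
`undefined = "trim"` to restrict the time axis to bins defined at all
cropped frequencies — the right choice when the tensor feeds the
decomposition, which does not handle missing entries.  On a
-1000:10:1000 ms grid the 40..1000 ms crop has 97 bins; the synthetic
generator's reference time axis instead uses 98 bins at 40..1010 ms so the
study-shaped tensor has the canonical 61 x 31 x 98 x 13 x 4 = 9,636,536
entries.

The z-transform uses defined bins only; it refuses rows with fewer than
two defined bins or zero variance rather than returning NaN.

## The five-way CP model (module `cpd`)

Stacking per-subject/condition maps yields the tensor
$\mathcal{W} \in \mathbb{R}^{I \times J \times K \times S \times C}$
(space x frequency x time x subject x condition).  The rank-$R$ CP model is

$$ w_{ijksc} \;\approx\; \sum_{r=1}^{R}
   a_{ir}\, b_{jr}\, c_{kr}\, d_{sr}\, e_{cr}, $$

with all factor matrices $A, B, C, D, E$ constrained non-negative for
interpretability: each component is a spatial topography, a spectral
profile, a temporal envelope, per-subject weights and per-condition
strengths that multiply, never cancel.

**Fitting.**  `nncpALS()` uses alternating least squares: each mode update
solves its exact non-negative least-squares problem with a Lawson-Hanson
active-set iteration on the normal equations (the Gram matrix is the
Hadamard product of the other modes' Grams; the right-hand sides come from
the matricised-tensor-times-Khatri-Rao product).  Exactness matters: it
makes the Frobenius objective provably non-increasing at every sweep, which
is asserted by a standing test.  Defaults: relative-fit tolerance $10^{-8}$,
at most 500 sweeps, 4 random restarts (entries $|N(0,1)|$), best fit kept.
CP has local minima — occasionally a restart drives a component to zero
(a lower-effective-rank stationary point); restarts with a surviving
component set are preferred, drawing up to two extra rounds of starts if
needed, all deterministic in the seed.  Without the non-negativity
constraint (available via `nonneg = FALSE`) the classical degeneracy watch
warns when two components' mode-congruence product falls below $-0.85$.

**Scale convention.**  CP scale is indeterminate per component.
`normalizeModel()` fixes the canonical form: unit-norm columns in all modes
but the last, all scale absorbed into the condition loadings.  All
inference reads condition loadings from canonical-form models only, so
differences are comparable across refits.

**Rank selection.**  `sweepRank()` decomposes at each candidate rank
(identical seeds across ranks) and tabulates explained variance,
$100\,(1 - \|\mathcal{W}-\hat{\mathcal{W}}\|_F^2 / \|\mathcal{W}\|_F^2)$,
and CORCONDIA.  CORCONDIA fits the least-squares Tucker core $G$ implied by
the CP factors and reports
$100\,(1 - \sum (G - T)^2 / \sum T^2)$ against the ideal superdiagonal
core $T$; values near 100 mean the data is adequately multilinear at that
rank, and the value collapses (often far below zero) when over-factored.
$G$ is computed by projecting the tensor with per-mode pseudoinverses —
algebraically identical to the dense least-squares core (the pseudoinverse
of a Kronecker product is the Kronecker product of pseudoinverses) and
tractable at any tensor size; a test pins the equivalence to a dense
solve on a small tensor.

A structural point the user should expect: a condition mode holding only
pre/post pairs has at most two distinct loading rows, so an exact drug-
structured rank-3 model has a rank-deficient condition factor and its
least-squares core is not defined — `corcondia()` then stops with an
over-factoring message, and on noisy data the value collapses instead.
This mirrors the empirical behaviour of core consistency on such designs,
where only the one-component model looks fully multilinear.  Exact-rank
diagnostics in the tests therefore use generic full-column-rank factor
sets (`makeCPTensor()`).

## Permutation inference (module `inference`)

`contrastModel(1..4)` builds the four condition sets: the no-drug proof of
concept (model 1: pre/post placebo plus both pre-drug baselines), the
two-drug comparison (model 2: pre/post levetiracetam and lamotrigine), and
each drug against placebo (models 3-4).  `buildModelTensor()` stacks the
per-cell maps in the contrast's label order.

The **master decomposition** (`masterDecomposition`, default rank 3) fixes
the component identities.  The observed statistic per component $r$ and
contrast is the condition-loading difference
$d_r = e_{\text{post},r} - e_{\text{pre},r}$ read from the canonical
master; model 2 additionally tests the between-drug
difference-of-differences.

The **null distribution** is built by permuting the subject x condition
grid of 3-D slabs and refitting *only* the subject and condition loadings,
with the space, frequency and time factors frozen at the master's values
(`refitLoadings`; the frozen modes are returned bit-identical).  Because
the refit objective depends on the tensor only through the projected array
$g_{scr} = \sum_{ijk} w_{ijksc}\, a_{ir} b_{jr} c_{kr}$, the tensor is
projected once and each of the (default 1,000) permutation iterations
operates on the small $S \times C \times R$ array — the loop costs
$O(n_{\text{perm}}\, S\, C\, R)$ after one pass over the data.  A standing
test keeps the shortcut equal to the naive full-tensor refit to $10^{-8}$.

**Permutation scheme.**  Two schemes are exposed.  `scheme = "joint"`
shuffles all $S \cdot C$ slab positions jointly.  The default,
`scheme = "within_subject"`, permutes condition labels independently within
each subject.  The default is the exchangeable-block scheme: under the
no-effect null, a subject's condition slabs are exchangeable with each
other, but slabs of *different* subjects are not — subjects differ in
overall loading.  The joint shuffle mixes that between-subject variability
into the null of the condition difference, inflating it far beyond the
statistic's sampling variation under the null, and the test becomes
conservative to the point of never rejecting.  The within-subject scheme is
calibrated: the package's acceptance suite measures its empirical type-I
error at nominal 5% over 200 replicate null data sets.  The joint scheme is
kept for sensitivity analysis.

**Decisions and p-values.**  Two-tailed p-values use the add-one
convention, $p = (1 + \#\{|d^\ast| \ge |d|\}) / (n_{\text{perm}} + 1)$,
which avoids $p = 0$ and respects the exchangeability floor
$p \ge 1/(n_{\text{perm}}+1)$.  The significance decision flags observed
values outside the empirical 2.5%/97.5% null quantiles, with ties resolved
toward non-rejection.  No correction is applied across the components or
contrasts of a model; the per-model tests are reported as-is.  Below 40
permutations the 2.5% tails are undefined and the test warns.

## The synthetic generator (module `synthdata`)

The generator emulates the structure the analysis is designed to find,
with three template components:

* **frontal-central beta** (15-30 Hz, peak 19 Hz, centred on FCz): early
  peak around 90 ms, suppression to ~400 ms, rebound from ~440 ms to a
  0.7-level plateau — the classic ERD/ERS shape;
* **occipital alpha** (6-13 Hz, peak 10 Hz, centred on Oz): absent early,
  rising from ~140 ms to a plateau by ~340 ms;
* **theta at the stimulation site** (4-6 Hz, centred on C3): peak between
  ~90 and 240 ms, fully suppressed from ~440 ms.

Spatial profiles are Gaussian bumps over 2-D coordinates from the packaged
61-channel 10-10-like montage — volume-conduction-like smoothness without a
head model.  Subject loadings are $|N(1, 0.2^2)|$: inter-subject
variability exists but no distribution is reported for it, so a mildly
dispersed positive family is the simplest defensible choice.  Condition
loadings start identical across conditions (no effect); the *drug effect*
is a per-component multiplicative factor on post-drug rows
(default `c(1, 0.7, 1)`: a 30% reduction of the alpha component, the
effect size used throughout the calibration and power suites; placebo
rows are never scaled).  Noise is i.i.d. Gaussian on tensor entries with
SD equal to `noiseSigma` (default 0.05) times the noiseless signal RMS —
the simplest exchangeable null consistent with z-scored inputs; a
t(4)-family switch provides heavier tails.  Components beyond the three
templates are random smooth non-negative profiles, flagged in the
metadata.  The absolute amplitude scale of components is not identified by
anything the package models, so scales are free parameters and all
assertions are relative (recovery, calibration, power).

`synthEpochs()` closes the loop for the time-frequency chain: per trial
and channel it sums band-limited oscillations whose carrier sits at each
component's spectral peak, with *random per-trial phase* (so the power is
induced, not evoked), an envelope following the temporal profile, and
broadband Gaussian noise at 1 kHz over -1..+1 s.

**What passing tests do and do not show.**  The generator produces exactly
multilinear signal plus exchangeable noise, smooth single-peak profiles
and no artefacts.  Real TMS-EEG has correlated, non-stationary noise,
residual muscle/ocular activity, non-multilinear structure, and subjects
whose topographies differ (not just their loadings).  Recovery and
calibration results on synthetic data validate the *implementation* — the
estimator finds the structure it models, and the test rejects at the
nominal rate when that structure is condition-exchangeable — not the
adequacy of the CP model for any particular recording.

## Problem sizes used by the test and acceptance suites

Chosen to exercise the full machinery at desk scale: recovery uses
16 x 12 x 20 x 8 x 4 tensors at 5% noise over 10 seeds; permutation
calibration and power use 200 replicate 8 x 6 x 10 x 6 x 4 data sets with
200 permutations each; oracle equivalences use tensors up to
10 x 8 x 9 x 6 x 4.  The study-shaped 61 x 31 x 98 x 13 x 4 configuration
is the generator default and is used for the bookkeeping checks (entry
count 9,636,536; a rank-3 model has 3 x (61+31+98+13+4) = 621 free
parameters, under 0.01% of the entries).

## Known limitations

* Missing-data CP is out of scope: tensors entering `nncpALS()` must be
  fully defined (use `undefined = "trim"` when building them from the
  time-frequency chain).
* Tucker and PARAFAC2 models, which relax CP's one-to-one mode coupling,
  are not provided.
* The permutation test fixes the first three factor matrices at the master
  solution; uncertainty in those profiles is not propagated into the null.
* CORCONDIA is undefined (and refused) when any factor matrix is exactly
  rank-deficient, which is structural for exact pre/post condition designs
  as discussed above.
* The HDF5 container stores arrays and labels, not FieldTrip/MNE metadata;
  it is a pipeline workspace, not an interchange format.
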