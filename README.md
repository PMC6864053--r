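# tensoreeg

Data-driven profiling of TMS-induced EEG oscillations by tensor
decomposition.

Transcranial magnetic stimulation (TMS) coupled with EEG probes cortical
excitability, and drugs acting in the brain change the induced (non-
phase-locked) oscillatory response. The response is intrinsically
multiway — it unfolds over electrodes, frequency, time, subjects and
pre/post-drug conditions — and window- or electrode-picking analyses
discard most of that structure. `tensoreeg` analyses the whole data set at
once: single-trial epochs become baseline-corrected z-scored induced-power
maps, the maps are stacked into a five-way tensor
(space × frequency × time × subject × condition), and the tensor is
decomposed with a non-negative canonical polyadic (CP / PARAFAC) model

$$ w_{ijksc} \approx \sum_{r=1}^{R} a_{ir}\, b_{jr}\, c_{kr}\, d_{sr}\, e_{cr}, \qquad A,B,C,D,E \ge 0, $$

fitted by alternating exact non-negative least squares (Lawson–Hanson
active set per mode). Each component r is one topography $a_r$, one
spectrum $b_r$, one temporal envelope $c_r$, per-subject weights $d_r$ and
per-condition strengths $e_r$. Rank selection is supported by explained
variance and the core consistency diagnostic (CORCONDIA), and a drug
effect is tested by a fixed-factor permutation test: condition labels are
shuffled within subject, the subject/condition loadings are refitted with
the spatial–spectral–temporal profiles frozen at the master solution, and
the observed post-minus-pre loading difference is compared with the
empirical 2.5%/97.5% null quantiles (two-tailed add-one p-values).

The package is aimed at EEG methodologists and pharmaco-EEG researchers.
Because the original recordings of such studies are rarely released, a
synthetic-data module generates factor-structured tensors and raw epochs
with known ground truth (frontal–central beta, occipital alpha, theta at
the stimulated electrode C3, injectable multiplicative drug effects), so
every stage — and every claim in the test suite — runs without any
download.

## Worked example

Simulate a study-structured data set with a 30% post-drug reduction of the
occipital-alpha component (the generator default), decompose it, and test
the drug contrasts:

```r
library(tensoreeg)

cfg    <- simConfig(nChannels = 16, nFreqs = 12, nTimes = 20,
                    nSubjects = 8, seed = 1)
gt     <- makeGroundTruth(cfg)
W      <- synthTensor5D(gt, cfg)
W
#> Tensor5D: 16 x 12 x 20 x 8 x 4 (122,880 entries)
#>   conditions: pre-LEV, post-LEV, pre-LTG, post-LTG

master <- masterDecomposition(W, decomposeConfig(rank = 3, seed = 1))
master
#> CPModel: rank 3 | 16 x 12 x 20 x 8 x 4 | fit 99.75% | 12 sweeps | converged | canonical
```

The fit explains 99.75% of the variance (the generator adds 5% noise).
Components come out in arbitrary order; congruence matching against the
ground truth identifies them — here fitted component 3 is the alpha
component (spectral peak 9.5 Hz):

```r
congruence(master, groundTruthModel(gt))$matching
#> [1] 1 3 2
W@freqs[apply(factorMatrices(master)[[2]], 2, which.max)]
#> [1] 17.6  4.0  9.5

res <- permutationTest(W, master, contrastModel(2), nPerm = 1000, seed = 1)
resultTable(res)
#>   component                                    contrast   observed        p decision
#> 1         1                          post-LEV - pre-LEV  0.0011015 0.188811    FALSE
#> 2         2                          post-LEV - pre-LEV -0.0003322 0.650350    FALSE
#> 3         3                          post-LEV - pre-LEV -0.2995789 0.000999     TRUE
#> 4         1                          post-LTG - pre-LTG  0.0002315 0.793207    FALSE
#> 5         2                          post-LTG - pre-LTG  0.0005153 0.470529    FALSE
#> 6         3                          post-LTG - pre-LTG -0.3008519 0.000999     TRUE
#> 7         1 (post-LEV - pre-LEV) - (post-LTG - pre-LTG)  0.0008700 0.456543    FALSE
#> 8         2 (post-LEV - pre-LEV) - (post-LTG - pre-LTG) -0.0008475 0.424575    FALSE
#> 9         3 (post-LEV - pre-LEV) - (post-LTG - pre-LTG)  0.0012730 0.963037    FALSE
```

The injected effect is recovered exactly where it was placed: the alpha
component's condition loading drops by ≈0.30 after either drug
(p = 0.000999, the add-one floor at 1,000 permutations), the untouched
beta and theta components stay null, and the between-drug
difference-of-differences is null because both drugs were given the same
effect.

The same analysis runs end-to-end through an HDF5 workspace
(`runPipeline()`, `exportTables()`), and the raw-epoch route is available
via `synthEpochs()` → `tfrPipeline()` → `buildModelTensor()`.

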