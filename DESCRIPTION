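Package: tensoreeg
Title: Tensor Decomposition of TMS-Induced EEG Oscillations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Data-driven profiling of transcranial magnetic stimulation (TMS)
    induced EEG oscillations by canonical polyadic (PARAFAC) tensor
    decomposition. Single-trial epochs are converted to baseline-corrected,
    z-scored induced-power maps with a Hanning-taper short-time Fourier
    transform, stacked into a five-way space x frequency x time x subject x
    condition tensor, and decomposed under non-negativity constraints with
    alternating exact non-negative least squares. Rank selection is supported
    by explained variance and the core consistency diagnostic (CORCONDIA), and
    drug-condition effects on component loadings are tested with a
    fixed-factor permutation test. A synthetic-data generator with known
    ground-truth components makes every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, MASS, rhdf5, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
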