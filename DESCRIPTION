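Package: urodyn
Title: Cystometry and External Urethral Sphincter EMG Analysis for Mouse
    Models of Lower Urinary Tract Dysfunction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of repeated urodynamic investigations (UDI) in awake
    mice: micturition-cycle detection on intravesical pressure traces,
    threshold-pressure estimation by the 65%-of-maximal-derivative rule,
    filling-volume computation, and no-cycle normalization for spinal cord
    injury (SCI) recordings with sustained high-pressure oscillations.
    External urethral sphincter EMG is quantified by a Hilbert-Huang
    transform (empirical mode decomposition plus analytic-signal spectrum):
    the threshold-to-peak interval is split into five equal parts and the
    duration-normalized 0-500 Hz energy of the before/during/after-voiding
    sections classifies each contraction as v-shaped (coordinated sphincter
    relaxation) or dyssynergic. Includes a phenomenological simulator of
    sham, partial bladder outlet obstruction (pBOO) and SCI recordings with
    ground-truth annotations, cohort summary statistics, and downstream
    differential-expression set comparisons (threshold filtering,
    sign-concordance partitioning of shared genes, enrichment-term keyword
    counts, delta-delta-Ct qPCR fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
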