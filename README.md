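# urodyn

Cystometry and external-urethral-sphincter (EUS) EMG analysis for mouse
models of lower urinary tract dysfunction (LUTD), aimed at labs running
repeated urodynamic investigations (UDI) in awake mice — spinal cord injury
(SCI, neurogenic) and partial bladder outlet obstruction (pBOO,
non-neurogenic) studies in particular.

## What it computes

**Micturition parameters.** On an intravesical pressure trace P_ves(t)
(cmH2O, 500 or 5000 Hz), micturition cycles are detected as
prominence-filtered pressure peaks that rise from and return to baseline.
Per cycle:

* `P_max` — the highest P_ves in the cycle;
* `P_thresh` — P_ves at micturition onset, defined as the earliest time in
  the 20 s before P_max where the first difference of the 0.1 s-smoothed
  trace reaches 65% of its window maximum;
* `V_filling = infusion rate / 60 x (t_thresh - t_start)` uL.

SCI recordings show rising pressure with sustained high-pressure
oscillations and no voiding; no cycle qualifies, and `normalizeNoCycle()`
instead normalizes P_ves to the recording minimum, takes `P_max` as the
normalized maximum, and extracts non-voiding contraction events.

**Sphincter coordination.** The EUS-EMG is band-passed (10 Hz to just below
Nyquist), notch-filtered, and decomposed by a Hilbert-Huang transform
(empirical mode decomposition + analytic-signal spectrum). The
threshold-to-peak interval of each contraction is split into five equal
parts — parts 1-2 "before voiding", part 3 "during voiding", parts 4-5
"after voiding" — and the 0-500 Hz energy per section, normalized by
section duration, is expressed as percentages. A contraction is **v-shaped**
(coordinated sphincter relaxation) when the during-voiding section has
strictly the lowest energy; per animal, the v-shape percentage is reported
over the analyzable contractions (>= 5 within 10 min, otherwise excluded).

**Cohorts and transcriptomes.** Group-by-week mean +/- SD tables, Welch
t-tests, repeated-measures ANOVA with Bonferroni post-hocs,
bladder-to-bodyweight ratios, DEG threshold filtering with named presets,
two-condition DEG intersection partitioned by fold-change sign concordance,
enrichment-term keyword counts, and delta-delta-Ct qPCR fold changes.

**Simulator.** `simulateRecording()` generates sham, pBOO and SCI
recordings (pressure, EMG with v-shaped/dyssynergic/flat modulation, scale
trace with randomly trapped voids) plus ground-truth annotations, so every
analysis step is validated by parameter recovery. `simulateDegTables()`
plants DEG overlaps with controlled sign concordance.

## Worked example

```r
library(urodyn)

sim <- simulateRecording(simParams("sham", durationS = 900,
                                   noiseSd = 0.02, seed = 7))
cyc <- detectCycles(sim$recording)
cyc[, c("cycle", "startTimeS", "tThreshS", "tPmaxS",
        "pmaxCmH2O", "pthreshCmH2O", "vFillingUl")]
#>   cycle startTimeS tThreshS tPmaxS pmaxCmH2O pthreshCmH2O vFillingUl
#> 1     1      0.458    293.1    295     22.99        12.35      48.77
#> 2     2    298.412    593.1    595     22.99        12.50      49.11
#> 3     3    597.938    893.1    895     23.01        12.42      49.19

summarizeRecording(cyc)
#>   nUsed pmaxMean pthreshMean vFillingMean fewerThanRequested
#> 1     3       23       12.42        49.02              FALSE
```

Three micturition cycles are found; each peaks near 23 cmH2O, crosses the
micturition threshold around 12.4 cmH2O roughly 2 s before the peak, and
fills ~49 uL at 10 uL/min. The summary row is the per-animal value a cohort
table would ingest.

DEG side, with a planted table of 21,751 nonzero-count genes:

```r
tbl <- simulateDegTable(21751, nUp = 174, nDown = 151, seed = 1)
res <- do.call(filterDegs, c(list(tbl), degPreset("sci_inclusion")))
c(res$nUp, res$nDown, res$fractionUpPct, res$fractionDownPct)
#> [1] 174.00 151.00   0.80   0.69
```

174 genes (0.8%) pass upregulated and 151 (0.69%) downregulated at
adjusted p < 0.1.

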