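---
title: "Methods: cystometry and sphincter-EMG analysis in urodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cystometry and sphincter-EMG analysis in urodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`urodyn` analyzes repeated urodynamic investigations (UDI) in awake,
restrained mice. A UDI recording is a synchronized set of series on one
uniform time base: intravesical pressure P~ves~ (cmH2O), optionally the
external urethral sphincter (EUS) EMG (V) and the cumulative voided volume
(uL) recorded by a scale beneath the animal. Two acquisition presets are
modeled: a 500 Hz arm infused at 10 uL/min (pressure only) and a 5000 Hz arm
infused at 20 uL/min with EMG.

The package answers three questions per recording:

1. **Micturition parameters.** Where are the micturition cycles, and what
   are P~max~ (highest P~ves~ in the cycle), P~thresh~ (pressure at
   micturition onset) and V~filling~ (infused volume from cycle start to
   threshold)?
2. **Sphincter coordination.** During each contraction, does the EUS relax
   while the bladder voids (v-shaped EMG energy profile), or does its
   activity rise with pressure (dyssynergia)?
3. **Cohort and transcriptome comparison.** Group-by-week summaries and
   tests of the per-animal metrics, and downstream comparison of
   differential-expression (DEG) tables between disease models.

# Threshold pressure: the 65%-of-maximal-derivative rule

P~thresh~ is defined operationally: smooth P~ves~ with a centered 0.1 s
moving average (50 samples at 500 Hz, 500 at 5000 Hz), take its first
discrete difference in the 20 s window before P~max~, and find the earliest
sample whose difference reaches 65% of the window maximum. The threshold
pressure is the *raw* pressure at that time.

Numerical choices:

* The derivative is the per-sample first difference of the smoothed series.
  The rule compares differences against a fraction of their own maximum, so
  per-sample versus per-second scaling cancels and the result is invariant
  to rescaling the pressure channel.
* Differences are left-assigned: the difference between samples *i* and
  *i + 1* belongs to sample *i*. On a constant-slope ramp every sample
  attains 100% of the maximum, so the window start wins ("first time
  reached"). The comparison is `>=`, so the maximal-derivative sample itself
  always qualifies.
* The moving average is centered with shrinking windows at the trace edges
  (no phase lag, output length preserved).
* A window whose differences are all non-positive has no rise to detect;
  the cycle is flagged and excluded from summaries.

Because the rule uses a single-sample difference, its noise sensitivity is
governed by the ratio of the noise SD after smoothing to the per-sample
signal slope. Recovery tests therefore run under a low-noise validation
condition (pressure noise SD 0.02 cmH2O); at that level the detected
threshold lies within 0.2 s of the planted truth. With the generator's
default noise (0.1 cmH2O, typical of a transducer/amplifier chain on a calm
animal) detection is still reliable for voiding contractions but threshold
times on the much shallower non-voiding oscillations become noisy.

# Cycle segmentation

The peak finder is not prescribed by the threshold definition, so the
package adopts a standard prominence-based design, exposed via arguments:

* Candidate contractions are local maxima of the smoothed pressure with
  topographic prominence >= 5 cmH2O and separation >= 10 s (defaults).
  Detection runs on a decimated (~50 Hz), additionally 1 s-smoothed copy of
  the trace; peak positions are refined at full resolution.
* A candidate becomes a micturition *cycle* only when it rises from and
  returns to near baseline: the cycle start is the pressure minimum since
  the previous cycle's end, that minimum must lie within 10% of the peak
  prominence of the recording-wide minimum, and the cycle end is the first
  return of the smoothed pressure to within the same tolerance of the start
  minimum.

The baseline conditions are what separate the two phenotypes: sham/pBOO
contractions return to baseline and qualify; the sustained high-pressure
oscillations after spinal cord injury (SCI) ride on a plateau far above the
recording minimum and never qualify, so `detectCycles()` correctly returns
an empty table. Such recordings are handled by `normalizeNoCycle()`:
pressure is normalized to the lowest value of the entire provided trace
(interpreted as the full trace, including any pre-infusion samples), P~max~
is the highest normalized value, and contraction events are found with the
same peak finder minus the baseline conditions.

V~filling~ is infusion rate / 60 x (t~thresh~ - t~start~) uL. Per-recording
summaries average the first three complete cycles (the per-animal-per-week
convention); recordings with fewer are averaged over what exists and
flagged.

# EMG quantification by the Hilbert-Huang transform

Preprocessing mirrors the acquisition chain: zero-phase Butterworth
band-pass (10-10,000 Hz, clipped below Nyquist when the sampling rate
cannot support it) followed by a mains notch (50 Hz default, the local
mains; configurable to 60 Hz).

No EMD implementation is available among the package's dependencies, so the
sifting algorithm is authored here: cubic-spline envelopes through maxima
and minima (mirror-extended by two extrema at each boundary), sift until the
normalized squared change between iterations drops below 0.2 or 10 sifts,
at most 10 IMFs. IMFs are subtracted successively, so IMFs + residual
reconstruct the input to machine precision. The analytic signal of each IMF
(frequency-domain Hilbert transform, reflection-padded to a 2-3-5-smooth
FFT length so arbitrary window lengths stay O(n log n)) yields the
instantaneous amplitude and frequency (central difference of the unwrapped
phase).

Timing individual voids is unreliable when voids are trapped in the fur, so
voiding is located structurally: the threshold-to-peak interval is divided
into five equal parts and the middle part is "during voiding". The first
two parts are "before" and the last two "after" — the partition itself
defines all three sections (a fixed-duration-flank alternative was
considered and rejected to keep every section inside the interval where the
contraction is defined). The energy of a section is the sum over IMFs and
in-section samples of squared instantaneous amplitude, restricted to samples
with instantaneous frequency in 0-500 Hz, divided by the section duration
in seconds (the before/after sections are twice as long as the during
section, so duration normalization matters). The EMD residual is excluded:
it carries the non-oscillatory trend, not sphincter activity. Percentages
are taken over the three duration-normalized energies, which by
construction sum to 100; contractions with zero in-band energy are flagged
and excluded.

A contraction is **v-shaped** when the during-voiding energy is *strictly*
the lowest of the three (ties are conservatively non-v-shape). Per animal,
the v-shape percentage is 100 x v-shaped / analyzable contractions, rounded
half-up to an integer at reporting time (normalization first, rounding
last); animals with fewer than 5 analyzable contractions within the first
600 s of analysis are excluded. The 10-min window is interpreted as the
first 600 s of the analyzed recording (configurable), since recordings are
longer.

# The simulator

`simulateRecording()` is phenomenological, not biomechanical. Sham/pBOO
pressure is baseline + a slow compliance ramp per cycle + a raised-cosine
voiding pulse whose end returns the trace to baseline; the raised cosine
was chosen for differentiability, so the 65%-derivative rule has a
well-defined crossing. SCI pressure ramps to a plateau and oscillates
sinusoidally around it without ever returning to baseline. EMG is Gaussian
white noise band-passed to a carrier band (default 50-450 Hz, within the
0-500 Hz analysis band), amplitude-modulated: suppressed to a configurable
fraction (default 0.2) in the middle fifth of each threshold-to-peak
interval (v-shape), scaled affinely with the noiseless pressure
(dyssynergic, envelope 0.3-1.0), or constant (flat). Voids occur at pulse
peaks with volume = infusion x elapsed time; each void is omitted from the
recorded scale trace with probability 0.3 by default (trapped voids).
Ground truth (void/peak/threshold times, planted pattern, trap flags) is
emitted alongside; ground-truth threshold times apply the derivative rule
to the noiseless sampled template.

Defaults where the acquisition description is silent are single, realistic
choices: intercycle interval 300 s (micturition every few minutes at
10-20 uL/min), contraction width 5 s, baseline 8 cmH2O, compliance slope
0.01 cmH2O/s, contraction amplitude 12 (sham) / 22 (pBOO) cmH2O so that
peak pressures land near the reported group means, SCI plateau 35 cmH2O
with 5 cmH2O, 0.05 Hz oscillations reached over 120 s, pressure noise SD
0.1 cmH2O, EMG carrier RMS 0.2 V with 5 mV additive noise. One top-level
seed drives all draws; identical parameters give bit-identical traces.

What the simulator does **not** emulate — and hence what passing recovery
tests do not certify on real data: movement artifacts and baseline drift,
colored (non-white) pressure noise, variable cycle lengths and amplitudes
within a recording, motor-unit structure in the EMG (it is an
interference-pattern model), post-void residual volume, and scale dynamics
(the volume trace is an ideal step function; the 5 Hz scale rate is carried
as metadata only).

# Cohort statistics and DEG comparison

Group summaries report mean and sample (n-1) SD — the divisor is a
convention choice, labeled SD. Cross-sectional contrasts use Welch's
unpaired t-test by default (robust to unequal variances; classic Student
available). Within-group time effects use a one-way repeated-measures ANOVA
with the animal as error stratum, equivalent to a two-way
subject-plus-time blocked linear model; animals with missing weeks are
dropped listwise with a warning. Post-hoc pairwise paired t-tests are
Bonferroni-adjusted by multiplication, capped at 1.

DEG filtering keeps the three significance presets distinct
(`pboo_inclusion`: raw p < 0.1; `sci_inclusion`: adjusted p < 0.1;
`volcano_strict`: adjusted p < 0.05, |log2FC| > 0.5, mean count > 50)
rather than reconciling them; exactly one p-criterion must be chosen per
call. Up/down fractions are computed over genes with nonzero mean counts
and reported to two significant digits, which reproduces both one-decimal
(0.8) and two-decimal (0.69) published-style figures from the same rule.
Shared-gene concordance uses the sign product of the two log2 fold changes;
an exactly zero fold change is classified discordant with a warning (no
direction can be concordant). qPCR fold changes use delta-delta-Ct with
assumed efficiency 2 and per-group means of replicate delta-Ct values.

# Problem sizes and test design

The test suite simulates at the smallest sizes that exercise each property:
sham recordings of 2-3 cycles (600-900 s), SCI recordings of 160-300 s
with a 60 s rise so five plateau oscillations fit, and recovery suites of
20 seeds per phenotype under the low-noise condition. EMD sanity checks use
1-2 s tones at 2000 Hz. The type-I-error calibration of the group test uses
2000 null datasets of 10 vs 10 animals. `scripts/acceptance.R` re-runs the
same computations from scratch under a caller-supplied seed and writes the
resulting quantities as JSON.

# Known limitations

* The threshold rule's single-sample derivative is noise-sensitive by
  construction; on shallow non-voiding oscillations with realistic noise,
  threshold times (and hence the EMG partition) carry sub-second jitter.
* EMD mode mixing is not controlled (no ensemble/noise-assisted variant);
  energy additivity across signals sharing a band is only approximate.
* The first SCI contraction borders the rising ramp and its lookback window
  may include ramp samples, biasing its threshold early.
* The repeated-measures ANOVA assumes sphericity; no correction is applied.
* DEG tables are consumed as given; no expression model is fitted.
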