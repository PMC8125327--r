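---
title: "Detecting driver stress from a single EMG channel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driver stress from a single EMG channel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgstress)
```

## The problem

Acute stress activates the sympathetic nervous system and raises the tonic
activity of postural muscles such as the trapezius. A single surface EMG
channel recorded during driving therefore carries information about whether
the driver is stressed, but the effect is subtle: raw EMG amplitude differs
across people by large factors (electrode placement, skin impedance, muscle
physiology), and within one person the waveforms of rest and stressed
driving look similar to the eye. `emgstress` implements a complete,
deterministic pipeline that turns a low-rate (15.5 Hz) EMG amplitude series
with rest / city-driving / highway-driving annotations into a binary
stressed / not-stressed classification, and quantifies every stage.

The pipeline is:

1. **Segmentation** — from each recording, five fixed windows are cut: one
   from the initial rest interval (label `NSC`, no-stress condition) and
   one from each of the two city and two highway intervals (`SC`, stress).
   The default window is 5 min (4650 samples at 15.5 Hz); windows of 1-5
   min support a window-length study.
2. **Rest-baseline normalization** — every window of a subject is z-scored
   with the mean and population standard deviation of that subject's rest
   window, `x~ = (x - mu) / sigma`.
3. **Feature extraction** — 17 statistical time features (STFs) per
   window.
4. **Feature selection** — Kruskal-Wallis rank test of each feature
   between the NSC and SC groups; the smallest-p features are kept.
5. **Classification** — soft-margin SVM (six kernels) and an MLP
   comparator under stratified 10-fold cross-validation, reporting
   accuracy, sensitivity, specificity and AUC.

## Normalization: why the rest baseline

The z-score formula admits two readings: normalize each window by its own
statistics, or normalize all of a subject's windows by the subject's
*rest* statistics. Self-normalization forces every window to unit
variance, destroying exactly the dispersion features that separate the
conditions; the rest-baseline reading preserves each stress window's
variance *ratio* to rest, which is the discriminating quantity. The
package therefore defaults to `normalization = "rest_baseline"` (the rest
window maps to mean 0, std 1 exactly; a stress window keeps variance
`var(stress)/var(rest)`), with `"self"` available for comparison. This
also makes all downstream features invariant to any positive affine
rescaling of a subject's raw signal — the inter-subject amplitude nuisance
is removed by construction.

## The 17 statistical time features

For a window `x_1..x_N` (population convention `1/N` throughout):
grouped mode; mean; range (`max - min`); variance; standard deviation;
impulse factor `max|x| / mean|x|`; square mean root
`SMR = (mean sqrt(|x|))^2`; shape factor over SMR; root mean square;
shape factor over RMS; crest factor `max|x| / RMS`; latitude factor
`max|x| / SMR`; and the 3rd-6th central moments normalized by RMS powers
(skewness, kurtosis, 5th, 6th moment); median.

Conventions that required a decision:

* **Range** is implemented as `max - min` (non-negative); a rank-based
  selection is unaffected by the sign convention in any case.
* **SMR** takes square roots of *absolute* amplitudes: normalized EMG is
  signed, and the square-mean-root statistic from the vibration-analysis
  literature is defined on magnitudes.
* **Even-length median** is the mean of the two central order statistics.
* **Moments 3-6** are normalized by powers of the RMS, not the standard
  deviation. This is deliberate: it follows the source formulas exactly.
  The conventional moments are recoverable through the identity
  `skew_conv = skew * (rms/std)^3` (and the analogous powers for the
  higher moments), which the test suite checks numerically.
* **Grouped mode** interpolates inside the modal histogram class,
  `L + c * d- / (d- + d+)`, with `d-`/`d+` the count differences to the
  left/right neighbour classes, leftmost class on ties, and the class
  midpoint when both differences vanish. The binning behind the grouped
  mode is not fixed by the source analysis; the package defaults to the
  Sturges rule `ceiling(1 + log2(N))` over `[min, max]`, configurable via
  `bins`.

All 17 implementations are certified against an independent
literal-transcription oracle (explicit loops and sums) to 1e-10 relative
error on random windows.

## Feature selection

EMG-derived features are strongly non-Gaussian, so group separation is
tested with the Kruskal-Wallis rank statistic (tie-corrected, chi-square
approximation) rather than ANOVA. Features are ranked by p-value; the
default selection keeps the `top_k = 2` features below `alpha = 0.01`.
Because the test is rank-based, the p-value is invariant under strictly
increasing transforms — variance and standard deviation always receive
identical p-values, and both are reported.

The selection also honours an explicit exclusion list (default: median
and SMR). In the reference analysis these two features reach small
p-values yet visibly overlap between conditions in their box plots, which
degrades the classifier; since there is no quantitative rule behind that
judgement, the package encodes it as configuration rather than inferring
it.

Under rest-baseline normalization with 10 subjects, a perfectly
separating feature attains the Kruskal-Wallis p-value of
`1.1157e-06` for 10-vs-40 groups — the floor observed for variance and
standard deviation on the default cohort.

## Classification

Six SVM configurations are compared: linear, quadratic and cubic
inhomogeneous polynomial kernels `(1 + u.v)^d`, and Gaussian kernels
`exp(-||u-v||^2 / s^2)` at three bandwidths derived from the predictor
count P — fine `sqrt(P)/4`, medium `sqrt(P)`, coarse `4*sqrt(P)` (the
fine/medium/coarse preset convention; a `literal` option gives `P/4, P,
4P` instead). The dual problem is solved to KKT optimality by libsvm via
the `e1071` package with box constraint `C = 1`; the contract is the solution,
not the solver trajectory, and the test suite verifies that free support
vectors lie on the margin and that the decision function is reproducible
from the stored dual coefficients and kernel.

The MLP comparator is a 2-10-2 network: tanh (bipolar sigmoid) hidden
units, two linear outputs with targets +/-1, trained by a damped
Gauss-Newton (Levenberg-Marquardt) least-squares scheme with analytic
Jacobian (damping 1e-3, x10 / /10 on rejected/accepted steps, at most
200 iterations), seeded initialization. Class = argmax of the outputs;
the decision value for the ROC is `output_SC - output_NSC`.

Evaluation uses stratified 10-fold cross-validation with seeded
shuffling: with 50 windows (10 NSC : 40 SC) each fold holds exactly 1
NSC and 4 SC windows, and each window is validated exactly once.
Features are standardized with the training fold's statistics. Accuracy,
sensitivity (on SC) and specificity (on NSC) come from pooled confusion
counts; AUC from the pooled out-of-fold decision values by the rank
(trapezoidal) method. With k = 10 equal folds the pooled accuracy equals
the mean of per-fold accuracies.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is exercisable
and testable without any data download. It emulates the *statistical
structure* the analysis relies on, not EMG electrophysiology:

* **Protocol** — rest 15 min, then city 13, highway 8, city 13, highway
  8 (57 min total), matching the recording durations and the
  1 + 2 + 2 interval structure of the driving study it models.
* **Noise model** — zero-mean Gaussian envelope noise, scenario standard
  deviation `baseline_scale * sqrt(multiplier)` with multipliers 1 / 2 /
  3 for rest / city / highway. The variance ratio is the discriminating
  statistic; Gaussianity is a modelling choice, not an inference about
  real EMG.
* **Inter-subject nuisance** — per-subject scales and offsets are
  log-normal (`lnorm(log 20, 0.6)`, `lnorm(log 100, 0.5)`), wide enough
  that un-normalized features overlap heavily across subjects, which is
  what motivates the rest-baseline normalization.
* **Transient bursts** — Poisson arrivals (per-subject rates uniform on
  1-3 events/min) of 0.5-2 s raised-cosine envelopes that multiply the
  local noise standard deviation up to a peak gain of 6. Bursts give the
  signal non-Gaussian tails (so kurtosis/skewness are non-degenerate)
  and, importantly, make short windows genuinely harder: a 1-min window
  sees a Poisson(1-3) burst count whose variability inflates the
  variance estimate unpredictably, while a 5-min window averages bursts
  out. This produces the rising accuracy-versus-window-length profile
  that motivates 5-min windows, with mean cubic-kernel accuracy rising
  from roughly the mid-90s at 1 min to ~100% at 5 min on default
  cohorts.

The burst gain and rate ranges were fixed once, by simulation at design
time, so that the default cohort exhibits the two qualitative properties
the pipeline is meant to demonstrate — variance and standard deviation
are the top-ranked features in ~100% of cohorts, and mean accuracy is
non-decreasing in window length — and they are not adjusted thereafter.

What passing tests on this generator do **not** show: performance on
real EMG, where amplitude distributions are skewed and non-stationary,
stress effects vary across subjects, and motion artifacts exist. The
default synthetic cohort is an easier problem than the real recordings
(near-perfect 5-min accuracy versus 96% reported on the real data);
the tests certify the pipeline's correctness and its qualitative
behaviour, not a field-performance claim.

## Numerical and degenerate-input choices

* Sample counts are `floor(minutes * 60 * fs + 0.5)` (round half up); at
  15.5 Hz all default window lengths give exact integers (1 min = 930,
  5 min = 4650 samples).
* A constant rest window (zero baseline variance) and an all-zero
  feature window (RMS = 0) are errors, not silent NaNs.
* An all-tied feature column gets H = 0, p = 1 (no information) rather
  than the NaN of the raw tie-correction formula.
* Fold-wise standardization guards zero-variance columns by leaving them
  unscaled.
* All randomness (cohort, folds, MLP init) flows from one master seed
  through deterministic child seeds; identical configurations give
  bitwise-identical study reports.

## Problem sizes used by the test suite

The packaged tests run the full 10-subject default study, 50-cohort
selection-recovery and 20-cohort window-length replications, and a
1000-replicate type-I-error simulation of the rank test; these sizes
were chosen as the smallest that make the binomial noise on the checked
rates comfortably smaller than the margins being asserted.

## Known limitations

* Binary classification only (stressed / not stressed); no three-level
  stress grading.
* No preprocessing (filtering, artifact rejection) — by design the
  pipeline consumes raw amplitude windows.
* The Physionet driving-stress waveform format is not read directly;
  recordings enter via the package's CSV dialect (or programmatically).
* Single EMG channel; no fusion with ECG, EDA or respiration.
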