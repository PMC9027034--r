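---
title: "Methods: single-channel EEG screening for dementia and MCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-channel EEG screening for dementia and MCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state EEG slows with Alzheimer-type dementia: power shifts from
the alpha/beta range toward delta and theta. A single dry prefrontal
electrode (Fp1) makes recording cheap enough for screening, at the cost
of heavy blink and movement contamination and a single noisy channel.
`eegscreen` implements a complete screening pipeline for such
recordings: artifact removal, spectral feature extraction referenced to
a control group, nonparametric feature selection, and cross-validated
three-class classification (dementia / mild cognitive impairment /
healthy, labelled from MMSE scores: 24 or below, 25--27, 28 or above).
Because comparable clinical recordings are rarely shareable, the
package ships a synthetic cohort generator with known spectral
structure and ground-truth artifact masks, so every stage is testable
end to end without any data download.

## Pipeline overview

```{r}
library(eegscreen)
spec <- cohort_spec(artifacts = artifact_spec(), seed = 1)  # 10/33/77 subjects
run <- run_pipeline(spec, default_config())
run$feature_tests
glance(run$cv)
```

Stages: band-limit to 1--30 Hz (4th-order Butterworth, forward-backward
so the filter is zero-phase) and z-normalise each recording (population
variance, exact contract); detect contaminated 2-s windows with a
derivative-sum score; decompose flagged segments by ensemble empirical
mode decomposition (EEMD), drop artifact components by cross-correlation,
and splice the reconstruction back; compute per-second power spectra
(short-time Fourier transform), average 1-Hz bins 1--45, normalise to
sum one, and add ten band means (delta 1--4, theta 4--8, alpha 8--13
with sub-bands 8--9 / 9--11 / 11--13, beta 13--30 with sub-bands 13--20 /
20--30, gamma 30--45 Hz); divide all 55 features by the control-group
mean ("relative power", control mean exactly 1); Kruskal-Wallis test per
feature with Bonferroni correction at the 5% level (Benjamini-Hochberg
FDR available); SMOTE-balance the classes and classify with an RBF-kernel
SVM under stratified ten-fold cross-validation.

## The synthetic generator

Each recording is a sum of band-limited Gaussian noise components (one
per generator band, white noise through a 4th-order Butterworth
bandpass, mixed with power proportional to the profile weights) over a
1/f^a aperiodic background, rescaled to a target RMS. Filtered noise
was preferred over inverse-FFT shaping to keep phases realistic. The
default profile emulates eyes-closed resting EEG at Fp1 in an elderly
population — delta-dominant, moderate theta and alpha, little beta and
almost no scalp gamma (weights 0.45 / 0.22 / 0.05+0.10+0.05 / 0.05+0.025
/ 0.01, aperiodic weight 0.25, exponent 1).

Group differences are deliberately **not** hard-coded in one direction.
The classical picture is spectral slowing in patients (more relative
delta/theta, less alpha), but the opposite ordering of relative delta
has also been reported when powers are expressed as ratios to a control
mean. `cohort_profiles()` therefore ships two presets, `"slowing"`
(patients slower; the default) and `"control_delta"` (controls carry
the higher relative delta), and asserts neither as truth.

Artifacts come with exact ground-truth masks. Blinks are biphasic
templates — a fast ~40 ms raised-cosine rise to the peak, a ~90 ms fall
overshooting to −0.3 of the peak, and a ~120 ms recovery — matching the
sharp deflection plus rebound of real frontal blink artifacts; a
purely unipolar smooth bump turns out to be nearly invisible to a
derivative-sum detector (its total variation is bounded by twice its
amplitude, which drowns in the total variation of ongoing broadband
EEG), and is also a poor model of real blinks. EMG events are
band-limited bursts with a smooth envelope; line noise is a continuous
sinusoid and, being continuous, is not part of the transient mask.
MMSE scores are drawn uniformly within each group's range (no score
distribution is assumed); amplitude units are arbitrary since the
pipeline z-normalises.

What the generator does **not** emulate: alpha bursting and other
nonstationarities, heartbeat and electrode-pop artifacts, inter-subject
variability beyond the group profile, and volume-conduction structure.
Passing tests on synthetic cohorts therefore demonstrates that the
machinery is correct and well-calibrated under the stated conditions,
not that the clinical effect sizes are recoverable from real data.

## Artifact detection

Each consecutive, non-overlapping 2-s window (a trailing partial window
is never scored) receives the score `sum(abs(diff(x)))` — the discrete
total variation. A literal *signed* derivative sum telescopes to
last-minus-first sample and cannot see bursts, so the absolute-value
reading is used. Windows are flagged when their score exceeds

```
median(scores) + k * one_sided_scale(scores),    k = 1.3 by default
```

where the scale is the median of the deviations *below* the median,
rescaled by 1/0.6745 for normal consistency. Artifacts only inflate
scores, so estimating spread from the lower half keeps the threshold
calibrated even when a quarter of the windows are contaminated; a
symmetric MAD is itself inflated by the artifact windows and a large
multiplier (e.g. k = 4) then misses essentially all 10x-amplitude
blinks. k = 1.3 puts the false-flag rate of clean windows near 5--8%
while detecting ≥ 90% of 10x blinks on the default background; both
the multiplier and an absolute threshold override are exposed in the
configuration, and the realised threshold is attached to every mask
for audit.

## EEMD cleaning

Flagged intervals are decomposed by EEMD: classical cubic-spline
envelope sifting (extrema mirrored at the boundaries; a candidate mode
is accepted when the Cauchy criterion `sum(m^2)/sum(h^2) < 0.2` is met
*and* its extrema and zero-crossing counts differ by at most one, with
at most 12 sifting passes; at most 10 modes; sifting stops when the
residual has fewer than three extrema). The ensemble averages the modes
of 100 white-noise-perturbed copies (tests and the standard suite use
50), noise SD 0.2 of the segment SD; the residual is defined as input
minus summed mean modes, so reconstruction is exact by construction.

Component rejection compares each mode against a reference by the
maximum over all lags of the absolute normalised cross-correlation
(biased estimator, FFT-computed) and drops modes exceeding 0.5. Two
references are implemented. Correlation *with the original segment*
(the default): in a flagged window the segment is dominated by the
artifact, so the artifact-carrying modes are exactly those that track
it. Correlation *between modes* (`reference = "imfs"`, with the mean
over the other modes) is also available; in practice EEMD modes are
close to orthogonal — observed pairwise maxima around 0.2--0.3 — so
this criterion essentially never fires at the 0.5 threshold and leaves
signals unchanged; it is retained for comparison. The residual (trend)
is never eligible for rejection, and a decomposition with a single mode
is kept under the between-mode reference (mean over an empty set is 0).
Cleaned segments are spliced back with a 0.1 s raised-cosine crossfade
inside the interval edges; samples outside flagged intervals are never
modified.

## Spectral features

The STFT uses 1-s non-overlapping windows (1 Hz resolution; trailing
partial dropped) with a Hann taper by default; a rectangular taper is
available for tonal unit tests. Spectra are normalised so that the
one-sided power summed over frequencies equals the window's mean square
value (taper-power compensated), making spectra comparable across
tapers (Parseval consistency). Bin features are the per-window means of
the integer bins 1..45 Hz scaled to sum to one; band powers are means
of constituent bins under half-open edges `[low, high)` (gamma closed
at 45), so a shared printed edge such as 4 Hz belongs to the upper
band, making delta = bins {1,2,3}, alpha1 = {8}, alpha2 = {9,10},
alpha3 = {11,12}. Broad alpha and beta are exact unions of their
sub-bands; all 55 features (45 bins + 10 bands) go into selection.

One acknowledged inconsistency is implemented as printed: the bandpass
ends at 30 Hz while features extend to 45 Hz, so gamma bins sit in the
filter's stopband and carry essentially no power by construction. The
configuration allows raising the bandpass edge to 45 Hz for internally
consistent runs.

Relative power divides every subject's features by the control-group
mean, which fixes the control mean at exactly 1 in every feature; a
zero control mean in any feature is a degenerate-input error naming
the feature.

## Selection and classification

Kruskal-Wallis (rank-based, tie-corrected, chi-square reference with
k−1 degrees of freedom; the fully tied case is defined as H = 0) is run
on each of the 55 candidates; the correction family is all 55 tests
jointly, Bonferroni by default — matching the described procedure — with
BH-FDR as the alternative since both corrections are named in the source
methodology. Selection uses corrected p-values at α = 0.05. Pairwise
rank-sum post-hocs over the three group pairs (Bonferroni over 3) are
reported for interpretation only.

SMOTE raises every class to the majority count; each synthetic sample
interpolates between a minority sample and one of its 5 nearest
same-class neighbours with a uniform factor. The SVM uses an RBF kernel
(one-vs-one voting), C = 1 and kernel width `1/(d·var)` by default —
the literature gives no hyperparameters, so the common heuristics are
used and recorded in the report. Features are standardised with
train-fold statistics because RBF kernels are scale-sensitive.

Cross-validation is stratified ten-fold. The `leakage` switch matters:
in `"safe"` mode (default) selection and SMOTE are fit inside each
training fold; in `"global"` mode both run on the full dataset before
splitting. Reported all-100% training metrics in this setting are the
signature of the global protocol, so it is reproduced as an explicit
option — but its test estimates are optimistically biased and `safe` is
the scientific default. If selection leaves no feature in some training
fold, all candidates are used for that fold rather than failing.

Metrics: accuracy is trace over total of the pooled confusion matrix;
multiclass sensitivity and specificity are macro-averaged one-vs-rest
rates, with classes absent from the truth excluded from the macro mean
(the source reports single values for a three-class problem without
defining them; macro averaging is the standard resolution).

## Numerical and design notes

* Intervals are half-open `[start, end)` in 0-based samples everywhere;
  recordings are tibbles (`sample`, `amplitude`) with metadata
  attributes; CSV is the canonical interchange format (a proprietary
  device format would add nothing testable).
* All randomness flows from explicit seeds; `derive_seed()` maps a
  master seed plus stage/subject tags to child seeds, so per-subject
  work could be parallelised without changing results.
* The z-normalisation contract is population variance, exact to 1e-9;
  sum-to-one normalisation exact to 1e-9; EMD completeness to 1e-8.
* Degenerate inputs fail loudly with classed conditions
  (`eegscreen_invalid_argument`, `eegscreen_degenerate_input`,
  `eegscreen_format_error`), and pipeline stage failures name the stage
  and subject.

## Problem sizes used by the test suites

Chosen to exercise the stated operating characteristics at desk scale:
the artifact suite is 50 recordings of 100 s (the study's recording
length) with five 10x-RMS blinks each and EEMD ensembles of 50; the
parameter-recovery experiment uses 30 subjects per arm at 30 s; the
type-I-error simulation uses 2,000 null datasets of 15 observations per
group; the end-to-end classification checks use 15 subjects per group
at 20 s with strongly separated band profiles (a machinery check, far
above any clinical effect size) plus a label-permutation null.

## Known limitations

* The headline clinical numbers of the motivating study were computed
  on private recordings and are not reproducible here; all acceptance
  checks are property-based on synthetic cohorts.
* A derivative-sum detector is blind to slow, smooth artifacts of
  moderate amplitude; it is an operating point chosen for blinks.
* EMD/EEMD are defined procedurally, not variationally; mode mixing is
  reduced, not eliminated, by the ensemble.
* Single channel only; no topography, connectivity, entropy or phase
  features; no EDF ingestion (CSV only).
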