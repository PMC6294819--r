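---
title: "Methods: acoustic dysarthria measures, correlation screening and FOG prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic dysarthria measures, correlation screening and FOG prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdspeech)
```

## The problem

Hypokinetic dysarthria (HD) is the motor speech disorder of Parkinson's
disease. It degrades phonation (breathy, unstable voice), articulation
(reduced tongue/jaw range) and prosody (monopitch, monoloudness, abnormal
pausing and rate). Freezing of gait (FOG) is a disabling axial symptom
assessed by the Freezing of Gait Questionnaire; items Q3-Q6 (each scored
0-4, 0 = absent, 4 = most severe) quantify freezing itself, and their sum
(0-16) is the total used here. Because speech and gait share axial motor
control, quantitative speech measures are candidate markers of current and
future freezing severity.

`hdspeech` implements that analysis as a tested pipeline with three stages:

1. **Feature extraction** — 16 acoustic measure types routed across a
   14-task recording protocol (sustained phonations, a diadochokinetic
   /pa/-/ta/-/ka/ task, read and spontaneous speech), yielding the 19
   measure-context pairs used clinically.
2. **Screening** — partial correlations (Pearson, Spearman, Kendall)
   between each feature and each FOG-Q item, controlling for age, gender,
   l-dopa equivalent dose, UPDRS III, BDI and ACE-R. A pair is flagged only
   when all three families agree at `alpha = 0.05`.
3. **Prediction** — gradient-boosted regression trees predicting the
   two-year change in each FOG-Q item from session-1 features under
   stratified 10-fold cross-validation with 100 repetitions, scored by MAE,
   RMSE, the estimation error rate `EER = 100 * MAE / r` (`r` being the
   observed range of the response), SSE and `R^2 = 1 - SSE / sum((y -
   mean(y))^2)`.

Since clinical recordings of this kind are not publicly available, the
package carries a first-class synthetic-data module that generates every
input with known ground truth; all quantitative claims in the test suite
are made against those planted values.

## Signal analysis

All frame-level tracks share one grid: 40 ms Hann-tapered frames advancing
by 10 ms, indexed by centre time.

**F0.** An autocorrelation tracker: per frame, the local mean is
subtracted, the frame is tapered, and the normalised autocorrelation is
divided by the window's own autocorrelation so a perfectly periodic input
scores ~1 at its period lag. Candidate peaks within the `[f0_min, f0_max]`
band (defaults 60-400 Hz) are scored with a per-octave penalty
(`octave_cost = 0.05`) against subharmonic picks — the normalised
autocorrelation of a real estimate can exceed its value at the true period
by ~0.02 at twice the period, so a weaker penalty demonstrably produces
octave errors on sawtooth fixtures. A frame is voiced when the winning
periodicity strength exceeds `voicing_threshold = 0.45` and the frame is
not silent; unvoiced frames carry `NA`, never 0 Hz. Parabolic
interpolation refines both lag and strength. On synthetic periodic signals
from 80-300 Hz the recovered mean F0 is within 1% of truth.

**Cycle extraction.** Jitter and shimmer need cycle-level quantities. Peak
picking on the raw waveform is ambiguous — secondary F1 oscillations within
a glottal cycle can top the search window — so cycle *timing* is taken from
the fundamental band: each voiced stretch is zero-phase bandpass filtered
to 0.5-1.5 times its mean F0, leaving one unambiguous positive peak per
cycle, refined parabolically. Cycle *amplitudes* are the maximum absolute
excursion of the raw waveform within each cycle. Cycles never span voicing
gaps, and stretches shorter than `min_cycles = 6` cycles are skipped. The
narrowband timing slightly attenuates very fast frequency modulation, so
planted-vs-recovered jitter tests assert monotone recovery and the analytic
FM case, not exact equality — the five-point quotients themselves are exact
formula evaluations, tested against independent arithmetic oracles at
1e-10.

**Formants.** Analysis resamples to `2 * max_formant` (default 11 kHz),
pre-emphasises (0.97), and fits an all-pole model per voiced frame by Burg
recursion with order `2 * n_formants`. The order is deliberately *not*
larger: with one surplus pole pair the fit places a spurious resonance in
the F1-F2 valley of vowels whose upper formants are sparse (reproducibly a
~1.2 kHz ghost pole on a 300/2300 Hz configuration), while one pair per
expected resonance recovers both targets within 10%. Pole angles inside
(90 Hz, ceiling - 50 Hz) with bandwidth under 700 Hz become candidates; the
lowest two are F1 and F2.

**Energy, pauses, nuclei.** Frame energy is Hann-weighted mean squared
amplitude — a rectangular window makes frame energy depend on how glottal
pulses align with frame edges (a ~2-3% intensity ripple on perfectly
amplitude-stationary synthetic voicing), which the taper suppresses.
Pauses are maximal runs, at least `min_pause = 0.25` s long, of frames more
than 25 dB below the utterance's 95th-percentile level, after trimming
leading/trailing silence (recording habit, not speech pausing); total
speech time (TST) is the trimmed duration, net speech time (NST) subtracts
pauses. Syllable nuclei are voiced intensity peaks above the same global
threshold separated by a 2 dB dip, in the style of the de Jong & Wempe
intensity-peak method.

## The measures

Phonation (sustained tasks): maximum phonation time (longest voiced
stretch), relF0SD (CV of F0), jitter PPQ5 and shimmer APQ5 (five-point
perturbation quotients, percent), mean HNR (`10 log10(r / (1 - r))` of the
periodicity strength, dB), DUV (unvoiced frame fraction within the trimmed
utterance), and F1/F2 dispersion. Articulation (running speech and the DDK
task): F1/F2 standard deviation and 1st-99th interpercentile range, DDK
rate (nuclei per second of trimmed utterance) and DDK regularity (SD of
inter-nucleus intervals). Prosody: relSEOSD (CV of frame intensity over
speech frames whose window lies fully inside a speech segment — frames
straddling a pause boundary measure the boundary, not loudness), relF0SD on
running speech, SPIR (pauses per minute of TST, configurable to NST), and
TSR/NSR (phones per second of TST/NST; scripted tasks carry configurable
default phone counts, unscripted speech requires a user-supplied count).

Two conventions are fixed package-wide and documented rather than assumed:
descriptive standard deviations use the sample convention (n - 1), matching
the defaults of the tools this analysis family is normally run with (Praat,
Matlab); percentiles use linear interpolation between order statistics.
Note that the rate definition count/duration carries an O(1/n) upward bias
on short event trains (n events span n - 1 intervals); at one-breath DDK
lengths this is within the stated 5% recovery tolerance.

## Partial-correlation screen

Pearson partials correlate the residuals of feature and item after linear
regression on the covariates (equivalent to the inverse-correlation-matrix
formula, asserted to 1e-10); p-values use t with `n - 2 - k` degrees of
freedom. Spearman partials rank-transform every variable first and are
invariant under strictly monotone transforms. Kendall partials use tau-b
(FOG-Q items are heavily tied integers) with the first-order recursion
applied iteratively over covariates; the p-value uses the normal
approximation with the classical tie-corrected null variance of tau-b. The
common shortcut — the no-ties variance with n reduced by k — is measurably
anti-conservative on 0-4 items (simulated type-I error 7.5% at nominal 5%,
n = 75), while the tie-corrected variant simulates at 4-5.5%; calibration
under the null decided this choice. Gender enters covariate adjustment as
a binary indicator.

No multiplicity correction is applied to the pass rule — the screen is
explicitly exploratory and the all-three-families agreement rule is itself
a conservative filter (its pass set is contained in each single method's) —
but Benjamini-Hochberg adjusted columns are reported for transparency.
Missing values are handled pairwise-complete with per-row n.

## Prediction

`fog_cv()` is the modelling entry point and returns a classed object with
`print`, `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot`
methods. Stratification of a continuous response uses quantile binning
(default 4 bins, fewer under ties) with round-robin dealing, giving
per-fold bin composition within one of proportional. Each of the 100
repetitions redraws folds from a seed derived from the master seed, fits a
gradient-boosted tree regressor (squared-error loss, 200 trees, depth 3,
learning rate 0.05, single-threaded for bitwise determinism) on the
training folds, pools out-of-fold predictions, and computes the five
metrics with `r` equal to the observed response range; reported values are
means and SDs across repetitions.

Feature selection is greedy forward by mean cross-validated EER with a
stopping tolerance of 0.1 EER points and a cap of 8, using a reduced
number of fold redraws (`selection_reps = 3`) per candidate. By default
selection runs once on the full data before evaluation; this mirrors how
such per-dimension feature lists are usually assembled but is optimistic,
since the held-out folds have seen the selection. `nested = TRUE` re-runs
selection inside every repetition instead. Full per-fold nesting would
multiply the fit count by roughly candidates x folds x repetitions and is
not offered; the optimism of the default is the documented trade-off.

Two cautions on interpretation. Boosted trees are piecewise-constant: on a
noiseless *linear* target at n = 80 the out-of-fold ceiling is around
`R^2 ~ 0.93-0.96` (edge extrapolation), which is the method's approximation
limit, not a bug. And the package's synthetic prediction targets are the
generator's continuous change scores; integer session-2 minus session-1
differences are also produced but quantise away small planted effects.

## The synthetic-data module

`synth_phonation` builds a glottal pulse train (impulses at fractional
sample positions, one-pole low-pass source shaping) with planted per-cycle
length jitter and amplitude shimmer (truncated Gaussian CVs), a cascade of
second-order resonators — five by default, roughly one per kHz as in real
vocal tracts; sparser configurations leave the all-pole analysis surplus
poles — white noise at a target harmonics-to-noise ratio, and optional
interior unvoiced gaps realising a planted unvoiced fraction.
`synth_ddk` emits Hann-enveloped voiced bursts at a planted rate and
interval SD. `synth_read_speech` concatenates continuous voiced segments
(knot-interpolated F0 and intensity trajectories, per-segment formants from
a random walk) separated by planted pauses; the realised RMS envelope is
divided out and the planted intensity envelope imposed, because harmonic-
resonance alignment otherwise leaks F0 variation into intensity. Knot
interpolation attenuates the planted F0/intensity CVs by roughly the
piecewise-linear averaging factor; tests therefore pin the zero-variability
cases and the pause/duration/count arithmetic, not exact CV equality.

`synth_cohort` draws covariates with plausible clinical marginals, loads
features and item latents moderately on them, and draws their residuals
jointly Gaussian so each planted (feature, item) partial correlation given
the covariates is exact before items are discretised to the 0-4 scale
(round half away from zero, clip). Discretisation attenuates a planted
rho = -0.5 to about -0.45 observed; the test suite measures this rather
than assuming it away. Non-positive-definite requests fail naming the
offending set. Change scores are planted linear functions of standardised
features plus Gaussian noise.

What the generators do *not* emulate: real phonetic segment structure,
coarticulation, room acoustics, microphone coloration, or non-Gaussian
clinical score distributions. Passing recovery tests therefore validates
the measurement and statistical machinery, not clinical performance on
real recordings.

## Problem sizes and numerical choices

The test suite uses short signals (0.5-5 s), cohorts of 40-80 subjects for
prediction and 75 (the study scale) for screening, 2000 null tests for
calibration and 100 seeds for power; the full repeated-CV protocol is
exercised once at 10 folds x 100 repetitions, n = 80, 8 features. Seeds
derive from a single master seed and stay below 2^31. Degenerate inputs
fail loudly: all-silent audio for pause detection, constant responses,
rank-deficient covariates, too few cycles/nuclei/frames for a measure.
Ties in quantile binning collapse bins rather than erroring. All output
files embed the package version, a configuration hash and the master seed,
and rerunning any stage with the same configuration is bitwise identical.

## Known limitations

The pitch tracker is single-pass (no Viterbi continuity), adequate for the
clean synthetic fixtures but less robust than production trackers on noisy
clinical audio. Formant tracking reports frame-wise lowest-two candidates
without inter-frame smoothing. Phone counts for speech rates are protocol
metadata, not recognised from audio. The non-nested selection default is
optimistic by construction, and EER's denominator is the observed range of
the specific response, so EERs are comparable across models of the same
response but not across responses with different observed ranges.
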