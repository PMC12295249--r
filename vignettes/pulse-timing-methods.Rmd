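---
title: "Pulse-timing analysis of synchronized cardiovascular waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-timing analysis of synchronized cardiovascular waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pulsekit)
library(dplyr)
```

## The measurement model

The package analyses four simultaneously recorded channels from a
catheterization-laboratory setting: an ECG, the central aortic pressure
above the aortic valve (CAP), the radial artery pressure from a distal
cannula (RAP), and the electrical bioimpedance of the contralateral wrist
(EBI), whose pulsatile component tracks arterial blood-volume changes.

Each cardiac cycle produces a pulse that leaves the heart at aortic-valve
opening and propagates down the arterial tree. Three delays relative to the
ECG R peak carry the timing information of interest:

* `PAT_CAP` — R peak to the onset (B point) of the central pressure pulse;
* `PAT_RAP` — R peak to the onset of the radial pressure pulse;
* `PAT_EBI` — R peak to the onset of the radial bioimpedance pulse.

Each arrival time contains the pre-ejection period (PEP), the
electromechanical delay between depolarization and valve opening. The
transit time `PTT = PAT_RAP − PAT_CAP` cancels the PEP, so

$$\mathrm{PWV} = \frac{L_{av \to ra}}{\mathrm{PAT_{RAP}} - \mathrm{PAT_{CAP}}}$$

is a PEP-free stiffness measure over the measured aortic-valve-to-radial
path length. A wearable device has no central catheter, so the package also
computes the complementary pulse wave velocity

$$\mathrm{CPWV} = \frac{0.8\,\mathrm{m}}{\mathrm{PAT_{EBI}}},$$

which divides a fixed representative path length by the EBI arrival time.
CPWV retains the PEP in its denominator; it is systematically lower than
PWV and is a *complementary* index, not an estimate of PWV. Its validity as
a cohort-level marker rests on the assumption that the PEP is reasonably
stable across resting, sinus-rhythm subjects — an assumption the package
cannot test and does not model.

## Processing pipeline

`build_patient_features()` chains the stages below; every stage is also
exported on its own.

**Smoothing and resampling.** All channels are smoothed with a
Savitzky–Golay filter (window 0.1 s, polynomial order 3) and resampled to
150 samples/s by cubic-spline interpolation. The window matches the
duration of the systolic upstroke, so rapid features are preserved while
broadband noise is suppressed; the ECG is deliberately over-smoothed by the
same filter because only the R-peak *time* is used downstream, and a
symmetric filter does not move a symmetric spike. All derivatives used
anywhere in the package are Savitzky–Golay polynomial derivatives with the
same window — raw finite differences of third order are noise-dominated at
150 Hz.

**Baseline removal.** The baseline of a pulse channel is defined as the
curve through the bases (per-beat minima) of the waveform. Because finding
per-beat minima requires beat positions, the pipeline bootstraps: coarse
onsets are detected on the smoothed trace, the baseline is estimated and
subtracted, and onsets are re-detected on the cardiac component. Two
estimators are provided:

* `"minima"` (default): shape-preserving piecewise-cubic interpolation
  through the per-beat minima, constant beyond the outermost knots. This
  implements the definition directly.
* `"hankel"`: the trace is embedded into a trajectory (Hankel) matrix with
  a window of 1.5 median RR intervals, the rank-2 reconstruction is taken
  as the slow component, a moving average spanning exactly one median beat
  period removes the residual at the cardiac frequency (that average nulls
  the beat frequency and all its harmonics), and the result is anchored
  through the per-beat minima. This estimator assumes the baseline (DC
  level plus drift) dominates the signal energy, which holds for raw
  pressure and impedance channels riding on large offsets.

**Beat onsets.** The onset (B point) is the time at which the first
derivative rises above `L_B = 0.15 · max(S′)`, with `max(S′)` the global
maximum of the first derivative; crossings are refined to sub-sample
precision by linear interpolation and a 0.4 s refractory interval (a
150 bpm ceiling, appropriate for resting sinus rhythm) suppresses secondary
crossings within a beat. Because the threshold is global, a single
high-amplitude artifact beat raises `L_B` for the whole trace; the
synthetic artifact modes are bounded (see below) so clean upstrokes always
still cross.

**Segmentation and synchronization.** Beats are half-open windows
`[onset_i, onset_{i+1})`; durations outside 0.3–2.5 s are dropped and
logged. ECG segments are the impedance beat windows shifted back by 300 ms,
which places exactly one R wave inside each window for physiological
arrival times. Beat indices are aligned across channels by onset proximity
(channel-to-channel arrival offsets are far smaller than an RR interval)
and only beats present in every channel are kept.

**Outlier rejection.** Three steps run sequentially per channel:

1. length filter — beats outside 0.6–1.4 times the median length;
2. a PCA detector scoring each beat by reconstruction error after
   projection onto the leading principal components (components retained to
   90 % variance, capped at one less than the number of fitted beats);
3. an empirical-copula detector scoring each beat by aggregated negative
   log tail probabilities per sample position (left, right and
   skewness-directed aggregates; the maximum of the three is the score).

Two implementation choices matter and were made deliberately. First, the
principal basis in step 2 is fitted on the half of the beats closest to the
column-median beat and all beats are then scored against it. A basis fitted
on all beats absorbs any repeated corruption pattern into the principal
subspace — at 10 % contamination the corrupted beats then reconstruct
themselves and score low (masking); the robust fit keeps the subspace
describing clean beat-to-beat variation only, which separates corrupted
from clean beats by more than three orders of magnitude in score. Second,
each scoring step may drop at most the top `contamination` fraction
(default 0.1) of beats, but a beat is only dropped if its score also
exceeds a gate — 1000 times the median score for the PCA step, 4 times for
the copula step — and a degenerate guard skips scoring entirely when all
beats are mutually indistinguishable. Unconditional fraction-trimming would
always sacrifice clean beats; combined across four channels through the
final keep-the-intersection rule it would discard several times the
nominal fraction. With the gates, measured clean-beat loss on synthetic
recordings is about 1 %, while every injected artifact is removed. The gap
between the gates and the measured score ratios (clean at most ~100x the
median, artifacts above 10^4x) is wide, so the gate values are not
delicate. The copula detector does not separate the synthetic artifact
classes on its own (its clean and corrupted score ranges overlap); it is
retained as a conservative second filter and its gate keeps it from
touching clean ensembles.

**Ensemble averaging.** Kept beats are resampled to the median beat length
of their channel's ensemble and averaged pointwise; the median duration is
retained so fiducial times measured on the averaged beat are reported on
the original time scale. Averaging n beats reduces uncorrelated noise by
1/sqrt(n), which the acceptance checks verify at n = 16.

## Fiducial points

Five landmarks are located per beat. For peripheral (EBI/RAP) beats: B is
the first sample of the period; C the first-derivative maximum between B
and the peak; D the global maximum; F the first positive-to-negative
transition of the third derivative after D; G the most negative
third-derivative excursion in `(tF, 2.5 tF]`. For central (CAP) beats: F is
the global pressure maximum; C the first-derivative maximum before it; D
the third-derivative maximum on `[tC, 0.95 tF]` (the inflection where the
reflected wave arrives); G the start of the first negative third-derivative
segment after the first-derivative minimum, searched up to halfway between
that minimum and the end of the beat.

Numerical choices: ties in argmax/argmin break to the earliest sample;
"positive/negative segment" means a sign run of at least `min_run = 4`
samples (shorter runs are sign chatter of a noisy third derivative and are
absorbed into their neighbours); points whose defining condition has no
solution are flagged undetectable rather than fabricated — a symmetric
raised-cosine pulse, for example, has no F because its third derivative
never turns negative after the peak. Detection is invariant to amplitude
scaling and offsets by construction. For CAP-D both an interval-argmax
formula and a segment-based description exist; the argmax on
`[tC, 0.95 tF]` is treated as normative because it is the more precise
statement and proves markedly more robust under noise.

## The synthetic generator

Real catheterization recordings of this kind are not publicly shareable, so
the package ships a generator that emulates the statistical structure the
analysis assumes and provides exact ground truth for every stage.

A beat template is a sum of smooth components in beat-relative time: a
gamma-kernel systolic wave with a sharp foot at the onset, a delayed
gamma-kernel diastolic (reflected) wave, a small raised-cosine bump at the
reflected-wave inflection, and a negative raised-cosine notch (the dicrotic
incisure), all multiplied by a fade window that returns the waveform to
zero before the next beat. The parameters were chosen so that (a) the five
landmarks exist, are strictly ordered and have unique, numerically stable
defining events; (b) the post-systolic slopes stay below 15 % of the
upstroke slope, so the onset threshold rule yields exactly one crossing per
beat; and (c) the foot sharpness is calibrated so that the threshold
crossing of the fully preprocessed signal lands within about a millisecond
of the true onset at typical resting heart rates — the smoothing filter
advances the crossing of an abrupt foot, so the foot exponent compensates.
Template ground-truth fiducials are always computed by brute-force
derivative analysis on a dense 10 kHz grid (`oracle_fiducials()`), never
read off the template parameters, keeping the oracle independent of both
the generator parameterization and the Savitzky–Golay detectors.

A recording concatenates per-beat templates whose onsets lag each ECG R
spike by the configured arrival times. RR intervals follow
`mean_rr · (1 + depth · sin(2π f_resp t))` plus Gaussian jitter with
standard deviation 1 % of the mean RR — respiratory modulation plus small
beat-to-beat variability. Defaults: 500 Hz native rate, 12 beats (the
working range of usable consecutive beats in this kind of recording is
5–15), mean RR 0.85 s, respiration 0.25 Hz at 5 % depth, arrival times
90/170/150 ms (central/radial pressure/impedance), 0.8 m path, per-channel
noise near 1 % of pulse amplitude and slow sinusoidal drift. Noise level
and artifact prevalence of real recordings are not published for this
setting; the defaults are conventions chosen to be realistic, not estimates
of any particular dataset.

Artifact injection corrupts `round(fraction · n_beats)` randomly chosen
beats across all channels, cycling two modes: amplitude scaling (x4 about
the beat minimum) and a cosine-tapered mid-beat step of twice the channel
amplitude. Both modes are continuous at the beat boundaries and preserve
the per-beat minimum, so the corruption cannot leak into neighbouring beats
through the smoothing filter or distort the baseline anchors — the labelled
beat is corrupted and only the labelled beat. High-amplitude noise bursts
were deliberately not used: their derivative spikes inflate the global
slope threshold enough to silence onset detection for clean beats, which
would couple the artifact's effect to the whole recording.

The cohort generator draws per-patient EBI arrival times from per-group
normal distributions (group 1, normal coronaries: mean 151 ms; groups 2–4:
mean 129 ms; sd 10 ms), giving group 1 a lower CPWV; the radial pressure
arrival is the EBI arrival plus a small positive offset and the central
arrival is drawn near 90 ms, so PWV runs in the 9–15 m/s range typical of
older subjects with cardiovascular risk. Risk-factor flags are Bernoulli
draws at the prevalences of a high-risk catheterization cohort
(hypertension 93 %, smoking 61 %, diabetes 18 %, untreated dyslipidemia
18 %, BMI > 35 and vascular disease 9 % each). `signals = FALSE` skips
waveform synthesis when only the truth-level cohort structure is needed.

What the generator does *not* emulate: pathology-specific waveform shapes,
wave reflections that change with vascular tone, baseline wander locked to
respiration, electrode-contact spikes, or arrhythmia. Passing tests on
synthetic data therefore demonstrate the correctness and numerical
stability of the processing chain under the stated assumptions — not
clinical performance on patient data.

## Cohort statistics

`spearman_with_ci()` computes the product-moment correlation of mid-ranks
(ties get average ranks), a Fisher-z interval with variance `1/(n−3)` by
default or a percentile bootstrap over resampled pairs, and a t-approximate
p-value. Rank correlation is the appropriate choice for small cohorts of
skewed physiological indices. Published analyses of this kind do not state
their interval method, so no attempt is made to match any particular
reported interval digit for digit.

`assign_cad_group()` implements the four-stage angiographic partition:
normal coronaries; at most 50 % diameter stenosis; 51–75 % lesions that are
not revascularization targets with one- or two-vessel disease; and 51–100 %
lesions that are revascularization targets or three-vessel disease. A
lesion above 75 % that is explicitly not a revascularization target falls
outside this partition; the function raises a classification-ambiguity
error instead of guessing, so the caller decides.

`compare_groups()` reports per-group medians and quartiles and a two-sided
rank-sum test, comparing group 1 against the rest or all pairs. The p-value
is computed by exhaustive enumeration of group-label assignments whenever
the smaller group has at most 8 members and the enumeration stays below
5·10^6 combinations (enumeration handles ties exactly, which the classical
exact distribution does not); beyond that budget the tie-corrected normal
approximation is used. The budget cap is a practical extension of the
"exact for small groups" rule: without it, an 8-versus-36 split would
require half a billion combinations.

## Problem sizes and limitations

The validation suite runs entirely on synthetic data at desk scale:
around a hundred randomized template beats per channel kind for the
fiducial checks, 20 simulated patients of 12 beats for velocity recovery,
one 100-beat recording with 10 % corrupted beats for the outlier stage, and
200 Monte-Carlo replicates for the group-contrast power estimate. These
sizes give stable pass/fail behaviour at fixed seeds while keeping the
whole suite around a minute.

Known limitations: the onset detector assumes resting sinus rhythm (the
0.4 s refractory and the template slope budget are tuned for mean RR up to
about one second; very slow rhythms can expose secondary threshold
crossings); CPWV inherits the pre-ejection period and is not interchangeable
with PWV; the Hankel baseline estimator assumes a dominant DC level; and
the copula outlier detector contributes little beyond the robust PCA step
on the synthetic artifact classes — on real data with different corruption
structure the balance between the two score steps may differ.
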