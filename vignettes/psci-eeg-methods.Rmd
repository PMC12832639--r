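---
title: "EEG spectral and microstate biomarkers for PSCI risk: methods"
author: "psciEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG spectral and microstate biomarkers for PSCI risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Post-stroke cognitive impairment (PSCI) affects a large fraction of stroke
survivors, and resting-state EEG carries candidate biomarkers for early risk
stratification: a shift of spectral power from alpha/beta toward delta/theta
(slow-wave dominance), and altered temporal dynamics of the canonical EEG
microstates A-D. `psciEEG` implements the complete analysis chain from raw
19-channel recordings to an interpretable per-subject risk prediction:

1. signal conditioning and quality control,
2. Welch band-power ratios (DAR, DTR, DTABR) over four scalp regions,
3. microstate segmentation (modified K-means with a deterministic
   template-combination search) and the temporal parameters MMD/MFO/MC,
4. three-arm consensus feature selection (LASSO, random-forest importance,
   Boruta),
5. five-family classifier training with repeated cross-validated grid
   search, calibration and decision-curve evaluation, and
6. exact per-subject Shapley attributions.

Because no public cohort exists for this problem, the package ships a
synthetic cohort generator that plants the group effects reported for PSCI
(higher DTABR, longer A/B microstate durations, less frequent microstate D)
so every stage is testable end to end.

## Signal model of the generator

A subject is simulated in two layers. A **label sequence** assigns one of
the four microstate classes to every sample: segment classes are drawn from
per-class occurrence weights with no immediate self-transition, and segment
lengths are geometric (memoryless) with a configurable per-class mean,
truncated at one sample. The geometric law is the simplest distribution
with a controllable mean; real microstate duration distributions are
heavier-tailed, which is one reason the *absolute* recovered durations are
biased low (see "Known limitations").

The **rendered EEG** at sample $t$ is
$x(t) = m_{c(t)}\,e(t) + \varepsilon(t)$, where $m_{c}$ is the active
class's template map (zero channel mean, unit norm), $e(t)$ is a shared
oscillatory envelope — coloured noise whose amplitude spectrum follows
$f^{-\gamma/2}$ over 0.5-40 Hz, multiplied per canonical band by the
band gains, RMS-normalized — and $\varepsilon$ is white sensor noise.
Amplitude units are arbitrary throughout: every downstream feature is a
ratio or a label statistic, so absolute microvolt scaling is irrelevant.

Defaults are the study conditions: group sizes 40/40, 1/f exponent 1,
sensor noise SD 0.05 (per-channel SNR of roughly 5 against the unit-RMS
envelope spread over 19 channels), control mean durations 50 ms with equal
occurrence weights; the PSCI-like group doubles the delta and theta gains,
lengthens the A and B mean durations by 40% and halves the D occurrence
weight. Age (round Normal(64, 8) clipped to 40-80) and sex
(Bernoulli(0.68), male = 1) match the reported cohort demographics loosely
and carry no outcome signal unless configured to.

### Template geometry

The four canonical maps are deterministic functions of electrode position
on an idealized 10-20 sphere: A and B are mirror-image diagonal gradients,
C an anterior-posterior gradient, D a radial (distance-from-vertex)
profile. The A/B gradient axes sit at ±60° azimuth from the anterior
midline. Two considerations fix that angle. First, a pure left-right
gradient and its mirror are perfectly anticorrelated, which would make A
and B indistinguishable under polarity-invariant clustering; the axes must
be oblique. Second, at ±45° the C map correlates 0.71 with both A and B,
and under noise C-labeled samples then preferentially flicker to A or B,
fragmenting C's segments and biasing its mean duration low relative to B
— a pure estimator artifact. At ±60° all pairwise correlations among
A, B, C balance at ±0.5 (D is orthogonal to the gradients by the montage's
symmetry), which removes the asymmetry while keeping the stated symmetry
classes.

The candidate banks for the combination search rotate each gradient axis
over an evenly spaced ±30° fan (7 angles for A, 5 for B, 6 for C) and vary
D's radial sharpness exponent (3 values), honouring the published
7 × 5 × 6 × 3 = 630 combinations.

## Preprocessing

Band-pass filtering is a designed 4th-order Butterworth applied forward
and backward (`signal::filtfilt`), i.e. zero-phase with an effective
8th-order magnitude — the usual toolbox semantics of "4th-order
zero-phase". The spectral arm computes PSD on the broadband
common-average-referenced signal (a 1-35 Hz filter would destroy the
30-40 Hz gamma band); only the microstate arm uses the 1-35 Hz filter.
Spherical-spline channel interpolation follows Perrin's formulation with
spline order m = 4, ridge regularization 1e-5 and a 7-term Legendre
series; the quality-control rule excludes a recording only when *more
than* 20% of samples are corrupted or *more than* three channels are
nonfunctional (boundary values are accepted). Artifact identification
itself is outside the package's scope — corruption enters as an explicit
per-sample mask, because component-level artifact removal is a visual,
non-algorithmic step.

## Spectral features

Welch PSD uses 4-s Hann windows at 50% overlap with density scaling, so
the frequency resolution is 0.25 Hz at any sampling rate. Band powers are
trapezoidal integrals over half-open bands [low, high) — delta 0.5-4,
theta 4-8, alpha 8-13, beta 13-30, gamma 30-40 Hz — so adjacent bands
never double-count a grid frequency. Regional aggregation averages the
channel band powers over each region's electrodes *before* forming
ratios (ratio of means): DAR = delta/alpha, DTR = delta/theta,
DTABR = (delta+theta)/(alpha+beta), over global (19), frontal (7),
central (5) and posterior (7) electrode sets, giving 12 features. The
regional partition is the standard anterior/central/posterior split of
the 10-20 montage and is configurable.

## Microstate stack

GFP is the per-sample population SD across channels. Peaks are local GFP
maxima extracted independently per 60-s segment with a 10-ms minimum
spacing (larger peak wins) and an outlier rule removing peaks above the
segment mean + 2 SD.

The modified K-means alternates (i) assignment of each peak map to the
template with maximal squared spatial correlation — polarity-invariant —
and (ii) template re-estimation as the dominant eigenvector of the
assigned centred maps. Because the GFP-squared-weighted correlation
objective and the eigenvector update optimize the same quantity, the
global explained variance

$$\mathrm{GEV} = \frac{\sum_p \mathrm{corr}^2(x_p, t_{a(p)})\,
\mathrm{GFP}_p^2}{\sum_p \mathrm{GFP}_p^2}$$

is non-decreasing across iterations; fitting stops when the improvement
falls below 1e-6 or after 500 iterations. The combination search runs
K-means from all 630 one-per-class initializations and keeps the highest
final GEV, breaking ties toward the lexicographically smallest candidate
index tuple, so the whole stage is deterministic.

Backfitting is per-sample winner-take-all on squared spatial correlation
over the 1-35 Hz signal (ties resolve A < B < C < D). Runs shorter than
8 ms or longer than 120 ms are relabeled unassigned; surviving runs are
never merged across an excluded gap, and unassigned samples stay in the
analysis-time denominator. Under these definitions the per-class
statistics obey exactly
$\mathrm{MC}(\%) = \mathrm{MMD}(\mathrm{ms}) \times
\mathrm{MFO}(\mathrm{Hz}) / 10$ and the MC values sum to the assigned
fraction. (Published microstate tables often violate this identity by
~10%, implying toolbox-specific denominators; this package keeps the
exact identity. The parameter called "Mean Median Duration" is defined,
and implemented, as a mean.)

## Feature selection

The three arms run on the standardized 26-column candidate table (age,
sex, 12 ratios, 12 microstate parameters):

* **LASSO**: `glmnet` binomial path with 10-fold cross-validated
  deviance; the consensus uses the nonzero set at the deviance-minimizing
  lambda (the 1-SE set is also reported — the published final features
  include variables absent from the 1-SE set, so the intersection must
  have used lambda-min).
* **Random forest**: seeded impurity importance ranking; retained =
  importance above the mean, capped at the top 10 (the published report
  shows a "green bar" cut with no numeric rule; this reproduces a
  7-of-26-style cut deterministically).
* **Boruta** (reimplemented): each iteration appends three shuffled
  copies of every candidate feature, fits a seeded forest and scores a
  hit when a feature's z-scored permutation importance beats the best
  shadow; two-sided binomial decisions at alpha = 0.05 with Bonferroni
  correction across all candidates. Two details matter for error
  control, and both were set after a simulation study of the selection
  dynamics (20-seed null and planted-signal tables): the shadow pool
  never shrinks as features are decided, and the correction stays at the
  full candidate count. With a shrinking pool the last undecided — i.e.
  luckiest — noise feature eventually competes against a single fresh
  shadow at an ever-looser threshold, and its fixed in-sample correlation
  wins persistently, producing false confirmations in roughly a third of
  null datasets. The enlarged (3x) shadow ensemble raises the
  per-iteration competition quantile above that dataset luck; with it,
  null tables confirm nothing and a planted log-odds-2 predictor is
  still confirmed in 20/20 seeds.

The consensus is the three-way intersection, emitted in random-forest
rank order; an empty intersection is a warning, not an error.

## Risk modelling

`fit_psci()` is the package's central estimator: stratified 70/30 split
(stratification prevents degenerate test sets at cohort sizes near 50),
per-feature standardization with training statistics only, then a grid
search over five families — random forest, RBF SVM, gradient-boosted
trees, L2 logistic regression, decision tree — scored by mean AUC over 5
repetitions of stratified 10-fold cross-validation with distinct fold
seeds. Grids are small published-default grids; rows are ordered from
stronger to weaker regularization so ties resolve toward the simpler
model, and the random-forest grid contains the reference configuration
(50 trees, minimum node size 10, unlimited depth). The family with the
highest CV AUC is refit on the full training partition and evaluated on
the held-out split: accuracy, AUC, Brier, sensitivity, specificity, PPV,
NPV, F1 at the chosen threshold; percentile-bootstrap 95% CIs; ECE/MCE
over 10 equal-width probability bins; and decision-curve net benefit
$\mathrm{NB}(p_t) = \mathrm{TP}/n - (\mathrm{FP}/n)\,p_t/(1-p_t)$
against treat-all/treat-none. The bias-corrected reliability curve refits
a logistic recalibration on each of 200 bootstrap resamples and averages
the curves evaluated on the original probabilities — the reference
analysis names the curve but not the algorithm, so this standard internal
validation recipe is the package's choice. The classification threshold
defaults to 0.5; `optimal_threshold()` maximizes Youden's J and returns
the midpoint of the lowest optimal probability interval (the published
48.83% threshold's derivation is unstated; Youden is the conventional
reading). The EPV planning utilities implement the worked formula
`ceiling(n_vars x EPV / (1 - incidence))` and the effective
events-per-variable ratio.

## Explanation

`shap_explain()` computes the exact interventional Shapley value of each
feature by enumerating all $2^p$ coalitions against a background sample
(default: 50 training rows): the value of a coalition is the mean model
output with coalition features set to the subject's values and the rest
drawn from the background. For the small consensus sets this pipeline
produces (p = 7 gives 128 coalitions) exact enumeration is cheap, and
additivity — base value plus contributions equals the model output —
holds to numerical precision for every subject and any model family, a
stronger guarantee than tree-specific path approximations.
`predict_subject()` is the command-line twin of a bedside tool: given one
subject's feature values it returns the PSCI probability, the class at
the 48.83% threshold and the signed contributions partitioned into
risk-increasing and risk-decreasing sets, with a research-use disclaimer.

## Problem sizes, numerical choices, degenerate inputs

Simulated cohorts in the test-suite and acceptance script use 250 Hz /
60 s recordings and the canonical 4-template K-means initialization —
sizes chosen so a full cohort analysis runs in seconds per subject while
every estimator operates far from its small-sample limits; the
630-combination search is exercised separately (it is deterministic, so
the count and the GEV-dominance property are what need testing). The
microstate rank-recovery study uses the clinical 3-minute recording
length, where the MMD rank statistic has adequate power. Zero-variance
feature columns pass through standardization centred (SD treated as 1)
and are never selected; spatially constant samples have zero GFP and
correlate zero with every template; empty K-means clusters keep their
previous template; single-class outcomes are errors everywhere a metric
would be undefined.

## What passing tests do and do not show

The generator produces exactly the structure the estimators look for:
one active template per sample, stationary statistics, white sensor
noise, no ocular/muscle artifacts, no volume-conduction mixing beyond the
template maps themselves. Recovery results on it validate the *code* —
identities, invariances, determinism, direction of planted effects — not
clinical performance. Two known gaps between this synthetic world and
real EEG: absolute recovered durations are biased low (label flicker at
envelope zero crossings fragments segments; rank order across classes is
preserved, absolute MMD is not), and per-sample backfitting diverges from
peak-interpolating toolboxes. Published cohort-level results (AUCs near
0.9 on clinical data) are not reproducible without the private cohort
and are not claimed.
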