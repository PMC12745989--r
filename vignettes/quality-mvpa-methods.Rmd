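---
title: "Methods: multi-voxel pattern analysis of visual quality perception"
author: "vqmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-voxel pattern analysis of visual quality perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqmvpa)
```

# The scientific question

When people look at degraded photographs — blurred, noisy, badly compressed —
early visual cortex receives an impoverished signal, yet semantic
understanding usually survives. This package implements a complete,
simulation-backed analysis chain for studying that phenomenon with
event-related fMRI: how perceived image *quality* (low / neutral / high)
modulates the *semantic* (face / object / scene) structure of multi-voxel
response patterns along the ventral visual hierarchy, whether the mappings
*between* regions reorganize under degraded input, and whether quality itself
can be decoded from combinations of regions even though no single region
encodes it strongly.

Seven bilateral regions of interest (ROIs) are analysed: calcarine, cuneus,
lingual and superior occipital gyrus (treated as low-level visual cortex),
and middle occipital, inferior occipital and fusiform gyrus (high-level).

# The experimental design generator

`generateDesign()` reproduces the structure of the underlying experiment: 14
participants, 8 runs of four 96-second task blocks, 18 image presentations
per block (3.5 s each) after a 4 s instruction period, with inter-stimulus
intervals jittered over {0.5, 2.5, 4.5} s. Two tasks alternate in a
palindromic QA–CC–CC–QA order on odd runs and CC–QA–QA–CC on even runs
(QA = quality assessment, CC = content classification). Each task has its
own 144 unique images — 16 per each of the nine category × quality cells —
and every image is shown exactly twice with at least one intervening trial
between its two presentations.

Three numerical choices matter here:

* **Exact timing.** The ISI solver (`solveIsiSchedule()`) works in integer
  tenths of a second: it enumerates every multiset of intervals whose sum is
  *exactly* the block's ISI budget (29 s with defaults), samples one
  uniformly, and shuffles it. The 96-second block identity is therefore an
  integer identity, not a floating-point approximation.
* **Repetition control.** Sequences come from a randomized backtracking
  shuffle (`shuffleWithMinLag()`) that provably satisfies the minimum-lag
  constraint or fails with an explicit error; infeasible multiplicities are
  rejected up front, and the search is exhaustive, so it cannot loop forever.
* **Cell counterbalancing across runs.** Each category × quality cell's
  presentations are dealt evenly across runs before within-run shuffling.
  The original experiment used a design-efficiency optimizer for the
  category-level sequence; since this package consumes trial-level betas
  rather than BOLD time series, hemodynamic efficiency is irrelevant, and a
  constraint-satisfying randomized sequence is the appropriate substitute.
  The even dealing additionally guarantees that every condition appears in
  both halves of the odd/even run split used for voxel-reliability
  estimation — at desk scale a fully random allocation can leave a condition
  empty in one half, which would make split-half reliability undefined.

Mean-opinion-score binning (`binQualityByMos()`) maps scores below 35 to
low, above 70 to high, and the closed interval [35, 70] to neutral; placing
both boundary values in the neutral bin is the literal reading of
"below 35" / "above 70" and is fixed here as the package's convention.

# The synthetic beta generator

`simulateBetas()` is a first-class module, not a test fixture: it encodes
the statistical structure the downstream analyses are designed to detect, so
every stage can be validated by parameter recovery.

Each image carries, per ROI, a 5-dimensional latent code:

* a **semantic part** — the one-hot category direction scaled by
  `semanticEffect` (default 1.5) and a gain in [0, 1] that depends on ROI
  and quality. Low-level ROIs default to gains 0.2 / 0.5 / 0.9 for
  low / neutral / high quality (semantic structure erodes as quality
  degrades); high-level ROIs use a constant 0.9 (semantic structure
  preserved). In high-level ROIs the semantic direction is additionally
  passed through an orthogonal *mixing transform*; when
  `qualityDependentMixing = TRUE` a different transform is drawn per quality
  level, planting a quality-dependent inter-region mapping, otherwise one
  shared transform is used.
* a **quality part** — the 2-dimensional embedding low = (0, 1),
  neutral = (1, 1), high = (1, 0), scaled by `qualityEffect` (default 0.4).
  This weak channel, present in every ROI, is what makes quality decodable
  from region combinations while keeping single-region quality information
  low. It is deliberately much weaker than the semantic channel.

Reliable voxels (`nReliableVoxels` of `voxelsPerUnilateralRoi` per
hemisphere) load on the latent code through a Gaussian loading matrix; the
remaining voxels carry pure noise. Noise enters at three levels with
different repetition behavior: image-level latent noise (sd 0.4) and
image-level voxel noise (sd 0.8) are shared by the two presentations of an
image — they are reproducible signal and set the noise ceiling together with
the planted structure — while repetition noise (sd 0.8) is drawn
independently per presentation. These defaults were chosen once to give
fMRI-plausible regimes: split-half voxel reliabilities well separated
between reliable and unreliable voxels, noise ceilings around 0.6–0.9, and
decoding accuracies clearly above chance but far from perfect.

What the generator does *not* emulate: BOLD time series, hemodynamic
convolution, scanner drift and motion, spatial voxel correlations,
between-participant anatomical variability, and attention or task effects.
Passing recovery tests on this generator therefore demonstrates that the
*analysis chain* is correct and calibrated — not that real cortical data
behave this way.

# Pattern extraction

`conditionProfiles()` computes, per voxel, mean betas for the 18 conditions
(2 tasks × 3 categories × 3 qualities) separately in odd and even runs;
`computeVoxelReliability()` correlates the two 18-vectors per voxel;
`selectReliableVoxels()` keeps the top `k = 100` per unilateral ROI
(deterministic tie-break toward the lower voxel index; undefined
reliabilities rank last). `buildRepresentations()` then concatenates the
selected left- and right-hemisphere betas (left first, canonical voxel
order — the concatenation order is arbitrary and fixed) into one vector per
image of length 2k (200 with defaults), keeps the two presentations
separately for cross-prediction, averages them *before* normalization for
the repetition-averaged variant, and z-scores every stored pattern across
its entries. Z-scoring per image-level pattern (rather than per voxel across
images) is the reading adopted for "normalizing the averaged pattern per
condition"; it removes amplitude differences between conditions and regions,
which is what correlation-based analyses require. Per-presentation vectors
are normalized by the same rule for comparability.

# Representational similarity analysis

`computeRDM()` uses the correlation distance 1 − Pearson r between pattern
vectors. The two model RDMs have closed forms: orthogonal one-hot semantic
labels give pairwise distance 0 (same category) or exactly 1.5 (different —
the correlation of two distinct length-3 one-hot vectors is −1/2); the
quality embedding places neutral equidistant (distance 1) from low and high,
which are √2 apart.

`informationContent()` correlates the strictly-upper triangles of a measured
and a model RDM (diagonal excluded, standard practice); per-quality semantic
content is computed on the sub-RDM of that quality's images — the only
reading that yields one value per quality condition. A Spearman variant is
available (`method = "spearman"`); Pearson is the default. Undefined
correlations (constant triangles) are flagged NA with a reason, never
silently zero.

Group statistics follow the heteroscedastic route: Welch's ANOVA
(`welchAnova()`, Welch–Satterthwaite denominator df) across quality
conditions with participants as observations, and Games–Howell pairwise
follow-ups (`gamesHowell()`, Welch t per pair referred to the studentized
range). The studentized-range algorithm is numerically undefined below 2
denominator df; such pairs report NA rather than a fabricated p-value.

# Inter-region mapping and noise ceilings

`fitMapping()` trains one ε-insensitive support-vector regressor with an RBF
kernel per target dimension (C = 1, ε = 0.1, γ = 1/d — the fixed
configuration used everywhere; no hyperparameter search). Inputs are
standardized with training-fold statistics only. A degenerate case is
handled exactly: if all training targets for a dimension fit inside a
2ε band, the ε-SVR solution has no support vectors and *is* the constant
function, so the midrange constant is returned.

To prevent shared trial-specific noise from inflating mapping scores, both
training and scoring are *cross-repetition*: presentations 1 of the source
predict presentations 2 of the target and vice versa, stacked for training
and averaged for scoring. Per test image the predicted and actual
200-vectors are compared with Pearson ρ and averaged across images and
directions (per-image scoring, then averaging, is the faithful reading of
correlating "the predicted and the true representation vectors").

`qualityGeneralization()` trains on three folds of one quality condition and
tests on the held-out fold *of the same fold number* in all three quality
conditions, 4 folds × 10 repeats by default. Folds are stratified by
content category within quality (a pure-random switch exists): at desk
scale, unstratified folds can lose an entire category, which distorts
cross-quality comparisons for reasons unrelated to the hypothesis.

The noise ceiling (`noiseCeiling()`) is the mean over images of the
correlation between the two presentation patterns, computed from the same
z-scored per-presentation vectors that feed cross-prediction (so ceiling and
model score are on one scale), averaged over images per participant and over
participants per ROI. It bounds achievable cross-prediction performance; the
test suite asserts the bound (with a 0.05 numerical tolerance) across all
simulated cells.

One point discovered during calibration deserves emphasis: a *null* dataset
for the mapping-generalization test — one in which the three test-quality
scores should be statistically indistinguishable — requires quality to
modulate *nothing*: shared mixing, quality-flat semantic gains, **and**
`qualityEffect = 0`. With graded gains or the quality channel active,
train-on-low models genuinely transfer differently across test qualities,
and the Welch ANOVA correctly rejects; that is a true positive, not
miscalibration. The calibration suites therefore use the fully
quality-invariant configuration as the null.

# Quality decoding

`decodeQuality()` regresses the integer quality targets (1 = low,
2 = neutral, 3 = high) on the concatenated repetition-averaged vectors of a
region set (200·|set| dimensions) with the same SVR configuration, under
repeated stratified cross-validation (4 folds × 10 repeats). Out-of-fold
continuous predictions are scored with SRCC and PLCC; with heavily tied
integer targets the printed untied rank formula does not apply, so SRCC uses
mid-rank Pearson-on-ranks, which reduces to the classical formula on untied
data. `groupPrediction()` averages *predictions* across participants before
scoring — averaging correlations instead would discard the noise-averaging
benefit that group prediction is meant to show. `compareToJoint()` tests
each region set against the all-region joint model (Welch two-sample t by
default — the unequal-variance form is the safer default even where a plain
independent-samples t is described; a pooled-variance switch exists) with
Benjamini–Hochberg correction at q = 0.1, flagging sets statistically
indistinguishable from the joint model. The random baseline draws continuous
uniform scores by default (integer draws available); the choice is
immaterial to its zero expectation.

# Reproducibility and problem sizes

Every stochastic step takes a seed; one master seed fans out to
(participant, repeat, stage) cells through a fixed arithmetic child-seed
scheme (`childSeed()`), and reruns are byte-identical. The test and
calibration suites run the full chain at a reduced scale chosen as the
package's validation configuration: 2 runs, 4 images per cell per task (24
images per pooled quality condition), 30 voxels per unilateral region with
20 reliable and 10 selected (20-dimensional patterns), 3–14 simulated
participants and 20 fixed seeds per rate estimate. These sizes keep every
property measurable (fold counts divide evenly, split halves stay populated)
while the full-scale defaults remain those of the study design.

# Known limitations

* The generator's linear-Gaussian latent model cannot probe robustness to
  heavy-tailed noise or nonlinear voxel responses.
* Welch/Games–Howell tests across quality conditions treat the three groups
  as independent although the same participants contribute to each; under
  the null the shared participant effects make the tests conservative.
* GLM estimation of betas from time series, atlas handling, searchlight
  analyses and classifier-based decoding are out of scope.
* The mapping analysis fixes C, ε and γ; conclusions about *relative*
  performance across qualities and region pairs are insensitive to this, but
  absolute scores are not tuned.
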