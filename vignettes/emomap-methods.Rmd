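---
title: "emomap: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emomap: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emomap)
```

## What the package computes

`emomap` implements a two-modality body-mapping analysis. On the neural
side, block-design motor and tactile localizer runs define somatotopic
sensorimotor maps (face, hands, trunk, feet), and emotion-recall runs
are tested for overlap with those maps. On the behavioral side, colored
body silhouettes are digitized into per-segment percentages of colored
pixels. Both modalities end in a 5 emotions x 4 segments "body-emotion
matrix" — an emotional homunculus in voxels and one in pixels — which
are compared subject-by-subject with a representational similarity
analysis.

Because raw scans for this kind of study are not distributable, the
synthetic-data module is part of the package's contract, not a test
fixture: it plants known ROI geometry, effect sizes, overlap fractions
and coloring fractions, and the pipeline is validated by recovering
those planted quantities.

## The GLM route

**Hemodynamic model.** Conditions are boxcars convolved with the
canonical double-gamma HRF (response gamma with shape 6, undershoot
gamma with shape 16, undershoot ratio 1/6; unit rate, so the response
peaks near 5 s). The generator and the design builder share one HRF
implementation (`canonical_hrf()`), so on noiseless data ordinary least
squares recovers planted betas to machine precision — this is by design:
the HRF is an assumption of the model, and the synthetic data embodies
the same assumption.

**Drift and scaling.** High-pass filtering uses the discrete-cosine
basis; for a cutoff of `1/128` Hz on a run of length `T` seconds the
basis has `floor(2 T / 128)` cosine columns plus the intercept.
Proportional global scaling multiplies each frame so its in-mask mean is
100; the mask defaults to voxels whose time-averaged intensity exceeds
one eighth of the global mean (the convention of standard SPM practice;
the original report does not state whether a mask was used, so it is a
configurable choice here). t-maps are invariant to a positive rescaling
of the run after global scaling, and a property test asserts that.

**First and second level.** The first level is a fixed-effects OLS fit
per voxel (`fit_first_level()`), with contrast t-maps
`t = c'b / sqrt(s2 c'(X'X)^-1 c)` and df = n − rank(X). Group inference
is a one-sample t-test across subject contrast images (df = n − 1).
Voxels with zero variance (which arise in exactly cancelling contrasts
and degenerate synthetic data) are set to t = 0 and flagged rather than
propagated as infinities.

**Thresholding.** Group maps use voxelwise p < 0.001 and cluster-extent
familywise correction at p < 0.05. Random-field theory is deliberately
not used: it is not reproducible from the published description and its
assumptions (smoothness estimation) are not meaningful for planted
binary truth. Instead the package uses a sign-flip max-cluster-size
permutation scheme, exact under the symmetric null: subject maps are
randomly sign-flipped (the same flips across contrasts where several
maps are combined), the largest suprathreshold cluster size is recorded
per permutation, and an observed cluster is retained when
`(1 + #{null >= size}) / (1 + n_perm) <= 0.05`. Connectivity is
26-neighborhood by default (6 available). Contrasts are directional, so
thresholding is one-sided by default, with a two-sided option. A
practical floor worth knowing: with n subjects there are only `2^n` sign
patterns, so cluster correction at alpha = 0.05 needs roughly n >= 6 for
the identity pattern not to exhaust the budget; the paired acceptance
test uses n = 15 with 500 permutations.

**Conjunction.** The whole-body map is the minimum-statistic conjunction
over all 8 localizer contrasts, tested against the conjunction null
(every effect present) — the stricter, well-defined reading of a
"single conjunction effect"; the global-null variant
(`conj_null = "global"`) is available. With the cluster step off, the
conjunction equals the intersection of individually thresholded maps,
which a test checks exactly.

**Segment specificity and disjointness.** Segment maps come from
"(target motor + target tactile)/2 − mean(other six contrasts)". When
two segments' thresholded maps claim one voxel (possible at lax
thresholds) the voxel goes to the segment with the larger contrast t;
the published group figures render non-overlapping colored areas but do
not state a rule, so the rule here is explicit and recorded in the mask
provenance.

## The silhouette route

**Template.** A synthetic body template (raster of a head, arms, torso
and legs with 4-segment labels) ships as generated code, not data. The
published instrument's pixel count is template-specific and therefore
not asserted anywhere; all percentages are relative to the template in
use.

**Registration.** Scans are aligned to the template by maximizing mutual
information (joint histogram with linear partial-volume binning —
a first-order Parzen window, the Mattes formulation) over a similarity
transform: translation, rotation, isotropic scale. Full affine is
deliberately excluded: shear would distort segment areas, and the
instrument's scans are near-rigid. The optimizer is a coarse grid over
translations (±12 px) and rotations (±6°) followed by two Nelder-Mead
refinements with shrinking parameter scales; both images are
pre-smoothed (sigma 1.5 px) and the metric is evaluated on every third
pixel. On the fixture template this recovers planted transforms of up to
10 px and 5° to within ~0.2 px and ~0.1°, against an acceptance bound of
0.5 px / 0.5°. A blank page has no ink signal and raises a
non-convergence error carrying the final metric value.

**Coding.** Colored pixels are classified by HSV hue windows — red
(hue < 20° or > 340°) as activation, blue (200°–260°) as deactivation —
with saturation ≥ 0.35 and value ≥ 0.15 floors; the original scanner
thresholds are unpublished, so the rule is exposed as arguments. Pixels
outside the body boundary are discarded. Activation minus deactivation
gives the {−1, 0, 1} subtraction map; group pixel t-maps are one-sample
t-tests per pixel with zero-variance flagging.

**Percentages.** `segment_percentages()` returns
`100 * colored / segment_count` per segment. Whether published
percentage tables used the activation channel alone or the subtraction
map is ambiguous; both are implemented (`channel = "activation"`
default, `"subtraction"` counts net-positive pixels).

## Convergence, hotspots, RSA, Bayes factors

**Convergence denominator.** "Convergence (in percentage)" does not
define its denominator in the source description. The default is
`mode = "mask"` — the fraction of the sensorimotor map reached by the
emotion map — because per-segment normalization is the only reading that
compares across segments of different sizes; `mode = "emotion"` is kept
for sensitivity analysis. Empty denominators yield `NA`, rendered as a
dash in reports (the convention for segments with no selective voxels).
Counts are grid-voxel counts; the voxel volume is recorded in the
manifest.

**Hotspots.** A segment is a hotspot when its value is within a fraction
tau of the row maximum; tau defaults to 0 (strict argmax, ties
included). The congruence table pairs self-report and fMRI hotspot flags
as +/− per emotion and segment.

**RSA.** Per subject, Pearson correlation between the flattened 5×4
pixel and voxel matrices (`mode = "direct"`); a `mode = "rdm"` variant
first builds 5×5 emotion-dissimilarity matrices per modality and
correlates their lower triangles — both are provided because the
source's description mentions similarity matrices but then describes
direct matrix correlation. The group test is a one-sample t on
Fisher-z-transformed coefficients (variance-stabilized); `fisher_z =
FALSE` reproduces a raw-r test, and the two agree in sign on every
instance (a property test). Constant matrices are excluded with a
warning; fewer than 3 usable subjects is an error.

**Bayes factors.** `bayes_one_sample()` pairs the classical t-test with
the JZS Bayes factor: Cauchy(0, r) prior on the standardized effect,
r = √2/2 by default (the common default of Bayesian t-test software,
consistent with the magnitudes the field reports), computed by
`integrate()` over the inverse-gamma mixture representation. An
independent oracle in the test suite integrates the noncentral-t
likelihood over the Cauchy prior directly; the two routes agree within
0.5% over a grid of n and t, and BF10(t = 0) < 1 for all n.

## The synthetic study

Defaults mirror the study design: TR 2 s; localizer blocks of 20 s task
/ 20 s rest cycling hands→feet→face→trunk; recall episodes of 14 s
alternating emotional and neutral, three per emotion; ratings on a 1–5
scale. Eight spherical ROIs (4 segments × 2 modalities, radius 3 voxels)
are pairwise disjoint across segments, plus one shared "whole-body" ROI
active in every localizer condition — the synthetic stand-in for regions
with broad receptive fields that make the conjunction map non-empty.
Emotion recall activates, per emotion, a planted fraction of each
segment's ROI and of the shared ROI, placed as a compact blob (voxels
nearest a random anchor) because real activation is spatially
contiguous and salt-and-pepper voxels would be — correctly — removed by
cluster correction.

Numbers the study does not report (effect sizes, noise) are calibration
choices fixed once: beta amplitude 2, Gaussian noise SD 1, cosine drift
amplitude 1, baseline 100 when global scaling is exercised. Planted
overlap fractions default to a plausible structure (face generally
strongest, sadness most embodied, anger least); silhouette coloring
fractions default to the same matrix so that pixel and voxel homunculi
are congruent — which is what makes planted-recovery testable. Noise in
self-report is modeled as truncated Gaussian jitter of the fractions
between subjects (SD 0.05) and between pre and post phases (SD 0.03).
All generators are pure functions of their seed (the caller's RNG state
is saved and restored), and fraction-times-count quantities round half
away from zero (`round_half_away()`), so counting oracles are exact.

What the generator does **not** emulate: physiological noise and its
autocorrelation, head motion, spatial normalization residuals,
anatomically realistic ROI shapes, scanner artifacts on silhouette
pages, and graded (non-binary) coloring. Passing tests therefore
demonstrate correctness of the estimators and inference machinery under
the stated model, not robustness to the full messiness of real data.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen as the smallest
that make each property measurable: a 24×24×18 (pipeline: 20×20×14)
voxel grid at 2 mm, 6–20 subjects, 200–500 permutations, 200 replicate
null datasets for familywise calibration, 1 000 replicates for RSA
type-I rate, and >10^5 voxel-tests for voxelwise calibration. The
end-to-end pipeline is deterministic given its seed, and rerunning it
byte-reproduces every CSV table.

Degenerate inputs are handled explicitly rather than by chance:
zero-variance voxels and pixels are flagged and zeroed; exactly
cancelling contrast combinations are snapped to true zero before
variance estimation (floating-point residue of order 1e-16 would
otherwise manufacture spurious t-values); empty convergence denominators
are missing values, not zeros; positive planted fractions that round to
zero voxels warn.

## Known limitations

- Cluster correction needs enough subjects for the sign-flip null to
  resolve alpha = 0.05 (about 6); below that, masks legitimately come
  out empty.
- Mutual-information registration is validated on the package's
  synthetic scans; heavily degraded real scans may need a wider search
  range (`max_shift_px`, `max_angle_deg`).
- The pipeline models one run per task; multi-run designs would need
  fixed-effects combination across runs before the second level.
- AR(1) prewhitening, motion regressors and slice-timing correction are
  out of scope; the synthetic noise model is white.
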