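---
title: "Methods: quantifying how spinal cord mask variability propagates into fMRI results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying how spinal cord mask variability propagates into fMRI results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spinal cord fMRI group analysis registers each participant's functional
data to a standard template, and the registration is informed by a manually
contoured binary mask of the cord in native fMRI space. Contouring is hard:
the cord is a small target (roughly 7 × 11 mm in cross-section at 1 × 1 × 3
mm voxels), the cord/CSF boundary contrast varies along the stack and can
even invert, and raters differ in experience. `cordmaskvar` provides the
full measurement-and-inference chain for asking how much this matters: how
variable are the masks, is that variability explained by rater or by
dataset, does it track image quality, and how far does it propagate —
through spatial normalization into participant-level and group-level
activation maps.

Because data of this kind are typically shareable only on request, the
package is driven by a synthetic phantom and rater simulator whose
parameters define the study conditions; every analysis stage is exercised
end to end on simulated data with known ground truth.

## The phantom and rater model

Each axial slice holds an elliptical cord (default semi-axes 5.7 voxels
left–right, 3.7 anterior–posterior, matching an ~11.4 × 7.4 mm cord at 1 mm
in-plane resolution) centered in a 44 × 128 grid; 25 slices of 3 mm. Gray
matter is a butterfly built from scaled ellipses — one vertically elongated
column per hemicord, whose superior and inferior ends form the dorsal and
ventral horns, bridged by a central commissure — kept strictly interior to
the cord (inside 0.85 of the cord ellipse). White matter is the remainder
of the cord; everything outside is CSF. The image is the per-voxel tissue
mean plus independent Gaussian noise; the masks are the noiseless geometry.
Tissue means are per slice: gray matter is brighter than white matter
(defaults 115 vs 100, the T2\*-weighted ordering), and the CSF mean follows
a per-dataset profile (baseline ratio to white matter drawn in 0.90–1.55,
drooping toward inferior slices) so that some slices show an Adjacent:SC
ratio below 1 — the contrast-breakdown regime seen in real acquisitions,
where susceptibility effects and CSF flow can make fluid voxels darker than
tissue.

A simulated rater applies, per slice and in order: a signed morphological
bias (`bias_voxels` dilations or erosions, 8-connected, in-plane), a random
contour translation (`slice_jitter_mm`, a Gaussian standard deviation in mm
rounded to whole voxels), and independent membership flips of boundary
voxels (`flip_rate`; the boundary is everything within in-plane Chebyshev
distance 1 of the mask edge). All rater errors act in-plane because
contouring is done primarily from the axial view. With all parameters zero
the rater reproduces the reference exactly; expected Dice decreases
monotonically in `flip_rate` (verified by Monte-Carlo in the test suite).
The default roster has eight raters with flip rates 0.02–0.27 and a common
0.3 mm jitter, spanning slicewise Dice from near-perfect to roughly
0.6–0.7 — a spread comparable to human raters of widely varying experience.

Slice difficulty is coupled to image quality through `difficulty_coupling`
(default 1.5): on low-contrast slices the effective flip rate and the image
noise are scaled up (flip rates capped at 0.45). This is the generative
mechanism behind the expected sign pattern — slicewise Dice correlates
positively with the Adjacent:SC ratio and negatively with the
adjacent-voxel CV.

Registration is emulated, not run: a rater's "registered" image is the
phantom image translated slice-by-slice by the negated centroid
displacement between the rater's and the reference mask (nearest-neighbor,
so masks stay binary and metrics stay exactly computable). A rater's
activation map is the reference participant-level map (constant-amplitude
blob in the stimulated hemicord over the middle two fifths of slices, plus
unit z-noise in the cord) displaced the same way, plus independent noise
with standard deviation `act_mismatch_sd × (1 − volume Dice)`. Both
couplings make downstream degradation a monotone function of mask
infidelity, which is the mechanism under study; they do not model the
nonlinear warping, interpolation, or GLM refitting of a real pipeline.

## Metrics

- **Dice**: `2|A∩B|/(|A|+|B|)`, per volume or per slice. Volume Dice equals
  the count-weighted aggregation of slicewise values. Both-empty scopes are
  an error (the caller decides exclusion).
- **Logit Dice**: `log(p/(1−p))` after clamping into `[ε, 1−ε]`, ε = 10⁻⁶.
  Clamping (rather than erroring) keeps perfect-agreement cells usable in
  the ANOVA; ε sets the ceiling at logit(1−10⁻⁶) ≈ 13.8.
- **Slice inclusion**: `n_trim` slices (default 1) dropped from each end of
  the stack, where image quality is poorest.
- **Adjacent region**: two iterations of in-plane 8-connected dilation of
  the reference mask, minus the mask, clipped at image borders. "Two
  voxels" is read as two one-voxel iterations (a Chebyshev ball), not a
  Euclidean radius; both the count and (in code) the construction are
  configurable.
- **CV of adjacent voxels**: sample (n−1) standard deviation over mean —
  scale-invariant. **Adjacent:SC ratio**: mean adjacent over mean cord
  intensity. Both per slice, from the reference mask only, so they are
  properties of the dataset, shared across raters.
- **GM:WM contrast**: mean gray-matter over mean white-matter intensity
  under fixed atlas regions; log-transformed for inference. On a noiseless
  phantom with gray matter brighter than white, the contrast is maximal at
  perfect alignment; the registration-proxy check uses a cord large enough
  (semi-axes 10 × 6) that 1–3 voxel shifts probe gray/white mixing only —
  with the default cord size, a 3-voxel shift already drags bright CSF into
  the atlas gray-matter region, which can raise the ratio again and mixes a
  second mechanism into the check.

## Inference

The per-cell response for the Dice ANOVA is the **mean of slicewise logit
Dice** over included slices (averaging on the logit scale; the volume-Dice
alternative is a one-line change in the table construction). The model is
additive (`rater + dataset`, no interaction) on a complete one-per-cell
design, so residual degrees of freedom are (R−1)(D−1): (7, 140) for 8
raters × 21 datasets, and (8, 160) when the reference joins the GM:WM
analysis as a ninth "rater". η² is factor SS over total SS; the three η²
sum to 1. A constant response is reported as the degenerate case (η² = 0, F
undefined) rather than 0/0.

The slicewise association between Dice and each image-quality outcome is
summarized per rater–dataset pair by Spearman's ρ (average ranks for
ties), Fisher-z transformed (atanh, clamped at |r| = 1 − 10⁻⁷), and
averaged across datasets within rater. Family-wise adjusted p-values come
from a max-T permutation scheme: within every rater–dataset pair
independently, the Dice values are permuted across slices (slices assumed
exchangeable); the pooled statistic is recomputed for every rater; and the
maximum absolute pooled Fisher z across raters is recorded. Two-tailed
adjusted p-values use the add-one convention `(1 + #{null ≥ |obs|}) /
(n_perm + 1)`, so they are never zero and never below `1/(n_perm+1)`.
Pairs with fewer than 3 usable slices or degenerate ranks are dropped from
pooling with a message; a degenerate correlation inside a permuted
replicate would contribute Fisher z = 0 rather than change the statistic's
dimension (with non-degenerate observed ranks this cannot occur, since
permutation preserves the rank multiset). The default 5,000 permutations
put the smallest attainable p at ~2 × 10⁻⁴.

## Activation comparison

The cord is split per slice into left and right hemicords by the single
left–right voxel column at the rounded center of mass (round-half-up, so
mirror-image geometry behaves symmetrically); the center column is
excluded. Ipsilateral pairs the hemicord with the same-side stimulus.
Spatial correlation between maps is Pearson on unthresholded z-values over
a region (Spearman available as an option), reported as Fisher z.
Group-level maps combine participant maps as a fixed-effects `sum/√k`;
group analyses run in the intersection of the datasets' cord masks. The
reference's group map is standardized voxelwise against the raters'
distribution using the sample (n−1) SD over the k raters; voxels with zero
rater SD are dropped with a warning. Thresholding uses a strict z > 2.3.

## Calibration and scale choices

The test suite and the acceptance script re-derive the pipeline's claims at
study scale (sizes chosen to keep a full run within minutes on one CPU):

- max-T calibration: 500 independent synthetic 8 × 21 × 23 tables with the
  outcome independent of Dice, 1,000 permutations each — the family-wise
  rejection rate at α = 0.05 must sit in the 95% binomial interval around
  0.05; with a rank correlation of 0.5 injected through a Gaussian copula
  (latent Pearson `2 sin(πρ/6)`), per-rater power is checked against 0.8
  over 100 replicates.
- sign recovery: the full default study (difficulty coupling on) must give
  pooled Fisher z > 0 for Adjacent:SC vs Dice and < 0 for CV vs Dice for
  every rater.
- rater gradient: a four-rung flip-rate ladder (0.02, 0.10, 0.22, 0.38)
  over 21 datasets, with jitter and difficulty coupling switched off so the
  flip effect is isolated (jitter is identical across rungs and would only
  add noise to the comparison; coupling saturates the per-slice flip cap at
  the top rungs and compresses the ladder). Mean logit Dice margins and
  mean ipsilateral Fisher z against the reference must both decrease along
  the ladder.
- exchangeable reference: 200 replicates of 8 rater maps plus one reference
  map drawn from the same distribution; z̄ must lie within ±3·SD[z]/√n of 0
  in at least 95% of replicates.

## What passing does and does not show

The phantom has independent Gaussian noise, a rigid per-slice geometry and
translational misregistration only. It contains no physiological noise
structure, no EPI distortion or susceptibility artifacts, no nonlinear
warps, no time-series (GLM fitting is out of scope), and rater errors are
stationary in time and unbiased in shape beyond the bias parameter. Passing
therefore demonstrates that the *measurement and inference chain* is
correct and calibrated — not that real raters or real registration behave
like the simulator. Conversely, the printed group-level correlation table
bundled with the package is real published data and anchors the
aggregation code to numbers obtained on an actual study.

## Numerical conventions

0-based voxel reasoning never leaks into R: all indexing is 1-based; the
slice axis is the third array dimension and increases superior → inferior
by convention of the manifest. Rounding of centroids and shifts is
round-half-away-from-zero (`floor(x + 0.5)`), not banker's rounding.
Seeds: every generator is a pure function of its parameters and seed;
study-level seeds derive deterministically from one master seed so adding a
rater or dataset never changes the others' data. Volumes are written as
NIfTI-1 with the voxel size in the header, masks as unsigned 8-bit, images
as 32-bit float (metric recomputation from disk agrees to storage
precision, ~10⁻⁵ relative).
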