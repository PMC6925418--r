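---
title: "How VOI delineation differences propagate through radiomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How VOI delineation differences propagate through radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Radiomics pipelines reduce a segmented tumour (the volume of interest, VOI)
to a vector of quantitative features and fit a classifier on them. The VOI
is usually drawn by hand, slice by slice, and different readers draw it
differently. `voirad` quantifies how much of a radiomics analysis survives
such delineation differences, stage by stage: feature values (via the
intra-class correlation coefficient), feature selection (via top-feature
overlap), and final prediction (via validation AUC, DeLong comparison, and
a cross-variant transfer matrix).

Delineation variability is emulated deterministically: the baseline mask is
perturbed slice-wise with morphological erosion (disk radius 3 px),
Gaussian smoothing (sigma 3 px, 7×7 window), and dilation (radii 3, 5,
7 px), giving the six variants `Baseline`, `Erosion`, `Smoothing`,
`Dilation`, `Dilation5`, `Dilation7`. Using graded, reproducible
perturbations rather than second-reader masks turns "how much delineation
difference is tolerable" into a dose–response question.

## The synthetic cohort generator

Patient MRI cannot ship with a package, so every stage is exercised on
synthetic cohorts from `cohort_spec()` / `generate_cohort()`. A case is
built as follows:

* **Lesion geometry.** A star-convex blob: per slice, the boundary is a
  radial function `r(theta, z) = r0 * z_profile(z) * (1 +
  irregularity * P(theta))`, with `P` a random low-order Fourier
  perturbation (modes 2–5, normalized to unit maximum) and an elliptical
  through-slice profile. Radius varies smoothly across slices, so the 3D
  mask is connected — matching slice-wise delineation practice. The spec
  validator guarantees a 7-voxel in-plane margin so even `Dilation7` never
  clips at the image border.
* **Lesion interior.** A correlated Gaussian random field: white noise
  smoothed with a Gaussian kernel whose width is the class-dependent
  correlation length (`corr_len_base` for class NM, plus `texture_effect`
  voxels for class TM), rescaled to a fixed SD via the closed-form variance
  of smoothed white noise. This is the simplest field in which texture
  features are class-informative with one interpretable knob.
* **Contrast and the intensity effect.** The lesion sits
  `lesion_contrast_sd` noise-SDs above a flat background, and class TM is
  shifted by a further `intensity_effect` noise-SDs. The whole lesion
  contribution is blurred with a small point-spread kernel
  (`psf_sigma = 0.6` voxels in-plane) before noise is added. The blur
  matters: all texture features are invariant to a constant shift of the
  in-mask intensities (quantization ranges are per-VOI), so a mean shift is
  detectable only through the lesion–background contrast expressed at the
  lesion rim by partial-volume mixing — exactly as in real imaging. Without
  the point-spread term the `intensity_effect` knob would be invisible at
  the native scale.
* **Acquisition noise.** i.i.d. Gaussian with SD `noise_sd`, added
  everywhere. No Rician model and no bias field: the pipeline assumes
  bias-corrected input, and plain Gaussian noise is sufficient for the
  statistical structure the analysis depends on.

Defaults: 64×64×16 voxels at 0.9×0.9×4.0 mm (anisotropic, MRI-like),
in-plane radius 8–12 voxels, irregularity 0.25, both effect sizes 0, and a
stratified 25% validation split (33% is the configurable alternative,
mirroring the two cohort designs the study emulates). The cohort is a pure
function of the spec, including its seed.

What the generator does **not** emulate: multi-sequence acquisition,
scanner-specific intensity distributions, spatially-structured anatomy
around the lesion, or reader-specific systematic bias. Tests passing on
these phantoms show the pipeline's statistical machinery behaves correctly;
they do not certify effect sizes on any real disease.

## Preprocessing

`normalize_intensity()` offers z-scoring (default, idempotent) and a
landmark method: a piecewise-linear map of the image's 1st/decile/99th
percentiles onto a fixed [0, 100] scale. The landmark variant is a
simplified single-image stand-in for training-set landmark normalization —
no cohort-level landmark averaging is performed, and it is documented as
such. N4-style bias-field correction is deliberately out of scope; input
images are assumed corrected.

## Feature extraction: 4 + 48 × 43 = 2068

Four geometric features come from the native-resolution mask:

* `volume_mm3` — voxel count × voxel volume;
* `size_mm` — longest axis of the inertia-equivalent ellipsoid,
  `2 * sqrt(5 * lambda_max)` of the coordinate covariance (recovers the
  diameter of a ball);
* `solidity` — voxel count over the rasterized convex volume (voxels whose
  centre falls inside the convex hull of the mask's voxel centres, computed
  by a compiled incremental 3D hull). The convex-image convention keeps a
  digital cuboid at exactly 1 and bounds the value by 1;
* `eccentricity` — `sqrt(1 - lambda_min / lambda_max)`.

Texture features are computed per combination of a 4 × 3 × 4 extraction
grid: isotropic scale {1, 2, 3, 4} mm × quantization algorithm {Equal,
Uniform, Lloyd} × grey levels {8, 16, 32, 64}. Each combination yields 43
features — Global (3: variance, skewness, kurtosis of the 100-bin in-mask
histogram), GLCM (9), GLRLM (13), GLSZM (13), NGTDM (5) — for 2064 textural
features. The grid is configurable; these defaults realize the printed
totals. The Global block depends only on the scale but is repeated in each
combination so every block is uniformly 43 features; the duplication is
visible in the feature names (`global.hist_variance.s1.Equal.g8`, …).

Numerical choices worth knowing:

* **Resampling** is trilinear (image) and thresholded-linear (mask, cut at
  0.5 − 1e−9). The target grid is built in mask-relative coordinates: its
  offsets depend only on the bounding-box extents, so whole-voxel
  translations reproduce features bit-for-bit. The threshold tolerance
  absorbs the rounding error of structurally-exact half weights; without
  it, a knife-edge voxel can flip between translated copies of the same
  input.
* **Quantization.** `Uniform` = equal-width bins on the in-mask range;
  `Equal` = quantile edges; `Lloyd` = Lloyd-Max scalar quantizer iterated
  to 1e−7 of the intensity range or 500 iterations from a uniform start,
  empty bins keeping their centroid. A constant VOI maps to level 1 with a
  warning, and downstream features take their defined degenerate values.
* **Matrices** (compiled): GLCM pools distance-1 pairs over the 13 unique
  3D directions into one merged, symmetrized, normalized matrix — merged
  pooling, not per-direction feature averaging. GLRLM pools maximal
  equal-level runs over the same 13 directions; GLSZM uses 26-connected
  zones; NGTDM accumulates |level − mean(26-neighbour levels)| per level.
  All four are verified exactly against brute-force enumeration oracles in
  the test suite.
* **Degenerate limits, never NaN**: single-cell GLCM has energy 1, entropy
  0, contrast 0, correlation 1; NGTDM coarseness is capped at 1e6 when its
  denominator vanishes; histogram skewness/kurtosis of a constant VOI are
  0/3.

## Robustness: ICC(2,1)

Feature robustness against a delineation variant is the two-way
random-effects, absolute-agreement, single-measurement ICC with the two
delineations as k = 2 interchangeable raters:

ICC = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E)).

Absolute agreement is the default because a systematic shift introduced by
a perturbation should count against robustness; the consistency form
(`"3,1"`) is available. Features with ICC ≥ 0.9 count as "excellently
robust". Constant feature vectors give an explicit `undefined` status —
excluded from counts and reported separately, never silently 0. ICC is
computed over all subjects by default (the training/validation distinction
is a modelling concept, not a measurement one); restricting to a split is a
matter of subsetting the feature table.

## Feature selection: mRMR, then 0.632+ bootstrap AUC

Stage 1, `mrmr_rank()`: greedy maximum-relevance minimum-redundancy (MID)
ranking to a 100-feature shortlist. Mutual information is computed on a
three-level discretization at mean ± SD — population SD with inclusive
outer bins, the reference convention; with sample SD and strict
inequalities a symmetric two-valued feature (e.g. a label copy) collapses
into the middle bin and scores zero relevance. Ties break to the lower
column index, so the ranking is deterministic.

Stage 2, `rank_top_features()`: the final 20 features are ranked by 0.632+
bootstrap AUC. "63.2% random data resampling" is read literally:
class-stratified subsampling without replacement of ⌈0.632 n⌉ per class
(the classic with-replacement bootstrap, whose expected unique fraction is
the same 63.2%, is available via `replace = TRUE`). The estimator blends
the apparent AUC with the mean bootstrap test AUC via the adaptive weight
w = 0.632 / (1 − 0.368 R), where R is the relative overfitting rate clipped
to [0, 1]; the closed-form fixed points (no overfitting → the common value;
maximal overfitting → 0.5) are unit-tested. The selection-stage classifier
is a ridge-regularized linear discriminant (ridge 1e−3 of the mean pooled
variance): fast, deterministic, and well-defined for collinear features;
the final classifier remains the random forest regardless. Stepwise
forward maximization is the default ranking mode (univariate is the
alternative); bootstrap splits are drawn once per step and shared across
candidates, and ties break by shortlist order.

Under permuted labels the recorded step scores sit slightly above 0.5 —
selection maximizes a noisy estimate over candidates — which the null
simulation in the test suite bounds well below the signal regime.

## Modelling and evaluation

For k = 1..20, a 150-tree probability random forest (ranger, single
thread, library defaults otherwise) on the top-k features is scored by
stratified 10-fold cross-validated AUC on the training cohort; the best k
(ties toward the smaller, more parsimonious k) is refit on the full
training cohort and evaluated once on the held-out validation cohort: rank
AUC, a 95% CI from the DeLong placement-value variance, and
sensitivity/specificity/accuracy at probability 0.5 (the operating
threshold is configurable; the study's thresholding rule is not pinned
down, and 0.5 is the neutral reading). Variant models are compared with
the Baseline model by the DeLong test for correlated ROC curves, and the
variant × variant transfer matrix applies each variant's model (with its
own selected features) to every other variant's validation features. Fold
counts reduce automatically (with a warning) when a class is smaller than
the fold count.

## Reproducibility and problem sizes

A single integer seed drives everything: cohort simulation, bootstrap
splits, CV folds and forest growth all derive their seeds from it, and the
pipeline writes every stage artifact to disk, reusing byte-identical
upstream artifacts on resume. Two runs with the same config and seed
produce bit-identical feature CSVs and evaluation reports.

The test suite exercises the full 2068-feature grid on single cases and
runs cohort-level statistical checks (null calibration, effect recovery,
ICC ordering across perturbation sizes) on a reduced 2-scale × Uniform ×
2-grey-level grid with a 30-feature shortlist, 8 final features and 200
bootstrap iterations — sizes chosen so the statistical properties under
test are unaffected while cohorts stay small. The acceptance script
reports, among other quantities, the validation AUC of a single null
cohort; with ~15 validation subjects the null AUC has an irreducible SD of
about 0.15, so individual draws scatter widely around 0.5.

## Known limitations

* Lesion phantoms are texture-homogeneous blobs on a flat background; real
  peritumoral anatomy (the mechanism behind disease-specific dilation
  effects) has no synthetic counterpart here.
* The landmark normalizer is per-image; no cross-scanner landmark training.
* Only slice-wise 2D perturbations with an exact Euclidean disk are
  implemented — deliberately, for oracle-checkable geometry; toolboxes
  using approximated disks will differ (e.g. 29 vs fewer pixels for the
  radius-3 element), and stochastic contour randomization is out of scope.
* Feature naming follows the `family.feature.s<scale>.<algo>.g<Ng>` schema,
  not IBSI nomenclature; definitions are the standard matrix statistics
  documented in the function reference.
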