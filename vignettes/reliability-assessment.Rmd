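---
title: "Assessing radiomic survival model reliability by image perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing radiomic survival model reliability by image perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipbm)
```

## The problem

Radiomic survival models map hundreds to thousands of quantitative image
descriptors of a tumour region to a time-to-event outcome. Their apparent
performance — a concordance index on a held-out cohort — says nothing about
*reliability*: whether the model would produce the same per-patient
prediction if the scan were re-acquired with slightly different patient
positioning, a different noise realization, or a slightly different tumour
delineation. Test–retest scans and multi-observer contours, the classical
way to probe this, are rarely available.

`ipbm` implements an image-perturbation-based alternative. Each patient's
image/contour pair is re-simulated many times under plausible randomizations;
the trained model predicts a risk score on every perturbed copy; and the
consistency of those predictions is quantified with the one-way
random-effects intraclass correlation coefficient, ICC(1,1), treating
patients as subjects and perturbations as raters. The same machinery scores
each *feature's* robustness, so that non-robust features can be screened out
(ICC > 0.75) and the model rebuilt on reliable inputs.

## The perturbation model

Three randomizations are composed per perturbed sample, applied to the raw
data before any preprocessing:

1. **Rigid transform** — rotation (uniform within ±`rotationDegRange`
   per axis, default ±15°, about the mask centroid, composed `Rz Ry Rx`)
   plus translation (uniform within ±`translationMmRange`, default ±5 mm),
   applied to image and mask *together*. The image is resampled with cubic
   B-spline interpolation (with the standard recursive prefilter), the mask
   with nearest neighbour, both back onto the input grid; out-of-grid image
   voxels are filled with −1000 HU. This mimics repositioning and
   resampling variability.
2. **Gaussian noise field** — i.i.d. zero-mean voxel-wise noise of SD
   `noiseSigmaHu` (default 20 HU) added to the image only, mimicking
   acquisition-noise fluctuations. Noise is spatially uncorrelated; a
   correlated-noise option would be a config extension, not a change to the
   method.
3. **Deformable contour randomization** — a dense random displacement field
   applied to the mask *only*, emulating inter-observer delineation
   variability. Per axis, white Gaussian noise is smoothed with an isotropic
   Gaussian of width `dvfSmoothnessMm` (an exact spectral convolution with
   periodic boundaries — appropriate for a stationary random field and
   independent of the smoothing width in cost), and the field is rescaled so
   the mean displacement magnitude over the mask foreground equals
   `dvfAmplitudeMm`; the mask is then backward-warped with
   nearest-neighbour sampling.

The DVF amplitude is not chosen by hand: `tuneContourAmplitude()` bisects it
until the mean Dice coefficient between original and randomized contours
hits a target operating point (default 0.85, tolerance ±0.01). Because the
same noise draws are reused at every candidate amplitude and the field
scales linearly, the objective is monotone and bisection is stable. The
smoothing width is the one remaining free parameter of the DVF protocol;
its default (16 mm) was calibrated on synthetic lesions of 15–25 mm radius
so that the *realized* operating point matches the published one on both
axes at once — mean Dice ≈ 0.85 **and** mean symmetric Hausdorff distance
≈ 5 mm. Rougher fields reach the same Dice with smaller but spikier
displacements (Hausdorff well above 5 mm); smoother fields behave like
coherent shifts (Hausdorff below 4 mm). Both quantities are re-measured
from scratch by `scripts/acceptance.R`. By default each patient receives
independent parameter draws per perturbation index (`sharedDraws = FALSE`);
sharing draws across patients is supported since either reading of the
protocol is defensible, and the choice did not change any qualitative
conclusion in our simulations.

## Feature extraction

Extraction follows the common IBSI-style pipeline: isotropic resampling to
1 mm (B-spline image / nearest-neighbour mask), soft-tissue resegmentation
of the intensity mask to (−150, 180) HU, and fixed-bin-count discretization
with N ∈ {4, 8, 16, 32, 64, 128} for texture features. Twelve images feed
the extractor: the original, three scale-normalized 3D
Laplacian-of-Gaussian images (σ = 1, 3, 6 mm), and eight single-level
*stationary* Coiflet-1 wavelet subbands (LLL…HHH). The undecimated
transform keeps subbands on the input grid so the mask applies per voxel;
filters are normalized so the LLL subband of a constant image reproduces
it, and boundaries use symmetric padding.

Per image the extractor computes 18 first-order statistics (on the
resegmented, undiscretized intensities — hence no bin-count suffix in their
names) and 73 texture features per bin count: GLCM 22, GLRLM 16, GLSZM 16,
GLDM 14, NGTDM 5. Fourteen shape descriptors come from the morphological
mask only. The full catalogue is therefore

```{r}
length(enumerateInventory())   # 14 + 12*18 + 12*73*6
```

Texture matrices use distance-1 neighbours over the 13 unique 3D
directions, with symmetric co-occurrences; per-direction feature values are
averaged. Entropy and Uniformity among the first-order statistics use a
fixed internal 64-bin discretization, since they need a histogram but carry
no bin-count suffix in the catalogue. Surface area and mesh volume are
computed on the voxel-union surface (face counting) rather than a marching
cubes mesh: surface area is overestimated relative to a smooth surface (so
Sphericity of a digital sphere is below 1), and MeshVolume coincides with
VoxelVolume on this representation. This is a documented simplification;
it is consistent across patients and perturbations, which is what the
reliability analysis needs. A plug-in extractor hook
(`extractFeatures(..., engine = )`) accepts an external engine producing the
same names if exact parity with another implementation is required.

## Modelling pipeline

Patients are split 70/30 with stratification by event status. Feature
selection is a two-stage filter fitted on the training cohort only:

* **Relevance** — 100 balanced subsamples (all minority-class patients plus
  an equal-size draw of the majority class, without replacement); per
  subsample each feature is median-dichotomized and tested with the
  log-rank test; features with p < 0.1 score a count, and the top 10% by
  frequency survive (ties broken by smaller mean p, then name, so the
  procedure is deterministic and column-order invariant).
* **Redundancy** — on the z-scored training table, while any pair has
  |Pearson r| > 0.6 the member with the highest mean |r| to the remaining
  features is removed. Iterating until clean guarantees the postcondition
  that no surviving pair exceeds the threshold; a single pass does not,
  which is why the iterative form is used. The threshold applies to |r|:
  redundancy is magnitude, not direction.

The survival model is a ridge-penalized Cox proportional-hazards fit
(Breslow ties), maximized by Newton's method with step halving to a 1e-7
gradient tolerance. Ridge is the natural penalty here: the redundancy
filter has already pruned collinearity, and L2 keeps every retained feature
identifiable. Backward recursive feature elimination removes, at each step,
the feature with the smallest absolute standardized coefficient; each
step's feature set is scored by stratified 3-fold cross-validation repeated
10 times, and the set with the highest mean validation C-index wins (ties
favour fewer features). CV scores fixed feature sets; it does not re-rank
features inside folds. The final penalty is tuned on the optimal set by
5-fold cross-validation over a 21-point grid `10^seq(-3, 2)`, ties going to
the stronger penalty. Risk scores are linear predictors on the training
z-scale; a patient at the training feature means scores 0.

## Reliability quantification

`icc11()` implements ICC(1,1) from the one-way ANOVA decomposition, with
the exact F-based 95% confidence interval and clamping of estimate and
bounds to [0, 1] (negative variance-ratio estimates are reported as 0).
Labels follow the conventional bands poor/moderate/good/excellent at
0.5/0.75/0.9, left-closed so 0.9 is "excellent". Feature robustness is the
ICC of each feature's raw (unstandardized) values across perturbations —
robustness is a property of the measurement, not of a training-set
transform. Model reliability is the ICC of the risk-score matrix; the
per-perturbation C-index distribution is reported descriptively alongside,
because a per-perturbation C-index has no subject dimension and therefore
cannot itself carry an ICC(1,1). Screening keeps features with ICC
strictly above 0.75 and reruns the whole pipeline; the improvement in model
ICC across repeated cross-validation splits is tested with a paired
Wilcoxon signed-rank test.

## The phantom generator

`generatePhantomCohort()` builds CT-like cohorts so that every stage is
testable without external data: a constant soft-tissue background
(~40 HU, plus 3 HU of white noise), one ellipsoidal lesion per patient
(semi-axes drawn from `lesionRadiusRangeMm`), and an internal texture
realized as white noise convolved with an isotropic Gaussian whose width is
the per-patient correlation length. The per-patient texture amplitude (HU)
and correlation length (mm) are the latent predictors: survival times
follow a Weibull proportional-hazards model (shape 1.2, scale 40 months by
default) whose log-hazard is linear in the standardized latents, and
censoring is an independent exponential time whose rate is calibrated by
bisection to the requested censoring fraction (±5%). All randomness flows
from one seed through per-patient sub-streams, so cohorts are
bit-reproducible. `generateIccTable()` is the matching direct simulator at
the feature level: `x_ij = mu + b_i + e_ij` with known variance components,
hence known true ICC.

What the phantom does *not* emulate: scanner reconstruction physics,
multi-lesion anatomy, anatomical context around the lesion, or PET. Tests
passing on phantoms therefore demonstrate the correctness and internal
consistency of the machinery — parameter recovery, calibration, the
direction of the screening effect — not clinical performance on real
cohorts.

## Numerical choices and problem sizes

* Interpolation: cubic B-spline (prefiltered) for images, nearest
  neighbour for masks, everywhere — perturbation and resampling share one
  convention.
* Whole-voxel translations are exact (no interpolation error), and a zero
  transform short-circuits to a direct copy.
* Hausdorff distance is the classical max–min over boundary voxels,
  computed via an exact Euclidean distance transform; the brute-force
  pairwise computation is kept as a test oracle.
* Discretization assigns the in-mask maximum to the top bin; a constant
  region maps to bin 1.
* Degenerate inputs fail loudly: empty masks, resegmentation that empties a
  mask, zero total variance in an ICC matrix, and contour randomization
  that sweeps a mask off the grid are all errors, not silent NAs. A
  constant feature entering the log-rank test returns p = 1 with a flag.
* The test suite runs phantoms at reduced sizes (26–48 voxel grids, 3–12
  perturbations, the GLCM/GLRLM subset of texture families) and the Monte
  Carlo checks at a few hundred replicates; these sizes were chosen as the
  smallest at which the statistical checks are stable, and the vignette's
  qualitative conclusions do not change at larger sizes.

## Known limitations

* The DVF deforms the mask only; image intensities are never warped, so
  intensity/texture changes under contour randomization come purely from
  the region shift.
* Voxel-union surface area biases Sphericity and SurfaceArea relative to
  mesh-based extractors; comparisons across extractors should use the
  plug-in hook.
* GLSZM/GLDM/NGTDM follow the common conventions (26-connectivity,
  dependence including the centre voxel, α = 0); other tools differ in
  small ways.
* The log-rank relevance filter dichotomizes at the median — the standard
  convention when a continuous feature enters a log-rank test, but a
  convention nonetheless.
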