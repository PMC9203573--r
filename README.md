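# ipbm — image-perturbation-based reliability assessment of radiomic survival models

Radiomic survival models predict time-to-event outcomes (e.g.
distant-metastasis-free survival) from thousands of quantitative descriptors
of a tumour region on CT. A good held-out concordance index does not mean
the model is *reliable*: re-scanning the same patient with slightly
different positioning, noise, or tumour delineation can change its
prediction. Test–retest images and multi-observer contours — the classical
probes of reliability — are rarely available.

`ipbm` simulates them instead. For every patient it generates perturbed
copies of the image/contour pair (rigid transform + Gaussian noise field +
randomized deformable contour, the latter tuned so the mean Dice overlap
against the original contour sits at a chosen operating point, 0.85 by
default). A trained model predicts a risk score on every copy, and
reliability is quantified with the one-way random-effects intraclass
correlation coefficient

    ICC(1,1) = (MSB − MSW) / (MSB + (k − 1) · MSW)

on the patients × perturbations risk-score matrix (patients as subjects,
perturbations as raters), with the exact F-based 95% CI. The same ICC
scores every feature's robustness, so that non-robust features (ICC ≤ 0.75)
can be screened out and the model rebuilt on reliable inputs.

The package is a complete workbench for this workflow:

* **Phantom cohorts** (`generatePhantomCohort`, `generateIccTable`) —
  CT-like volumes with an ellipsoidal, textured lesion whose latent texture
  parameters drive a Weibull proportional-hazards outcome; plus a direct
  subjects × raters simulator with known true ICC.
* **Perturbation** (`simulatePerturbationSet`, `rigidPerturb`,
  `addNoiseField`, `randomizeContour`, `tuneContourAmplitude`,
  `diceCoefficient`, `hausdorffDistance`).
* **Feature extraction** (`extractFeatures`, `enumerateInventory`) — the
  12-image filter bank (original, Laplacian-of-Gaussian σ = 1/3/6 mm,
  stationary Coiflet-1 subbands), 14 shape + 18 first-order + 73 texture
  features (GLCM/GLRLM/GLSZM/GLDM/NGTDM) per image per bin count
  ({4,…,128}): 5,486 features with defaults.
* **Selection** (`selectFeatures`) — bootstrap log-rank relevance filtering
  (100 balanced subsamples, p < 0.1, top 10% by frequency) then pairwise
  correlation redundancy filtering (|r| > 0.6).
* **Modelling** (`fitCox`, `rfeCox`, `tunePenalty`, `cIndex`) —
  ridge-penalized Cox (Breslow ties, Newton solver), backward RFE scored by
  repeated stratified cross-validated C-index.
* **Reliability** (`icc11`, `featureRobustness`, `screenFeatures`,
  `modelReliability`, `subgroupAnalysis`, `crossValidationAnalysis`).
* **Orchestration** (`runFullPipeline`, YAML configs, and a thin CLI at
  `inst/cli/ipbm.R`).

## Worked example

```r
library(ipbm)

# a small synthetic cohort: 18 patients, 26^3 voxels, textured lesions
cohort <- generatePhantomCohort(phantomConfig(
  nPatients = 18L, gridShape = c(26L, 26L, 26L),
  lesionRadiusRangeMm = c(6, 8), censoringRate = 0.35,
  hazardCoefficients = c(amplitude = 1.2, corlength = 0), seed = 42L))
outcomes <- cohortOutcomes(cohort)
split <- stratifiedSplit(outcomes, testFraction = 0.3, seed = 1L)

# three perturbed copies per patient
spec <- perturbationSpec(nPerturbations = 3L, rotationDegRange = 4,
                         translationMmRange = 2, noiseSigmaHu = 10,
                         dvfAmplitudeMm = 1.2, seed = 7L)
pset <- simulatePerturbationSet(cohort, spec)

cfg <- extractionConfig(filtersEnabled = "original", binCounts = c(8L, 32L),
                        textureFamilies = c("glcm", "glrlm"))
tab <- extractFeatureTable(cohort, cfg)          # 18 x 108 feature matrix
ptabs <- extractPerturbedFeatureTables(pset, cfg)

fit <- runModelingPipeline(tab, ptabs, outcomes, split$train, split$test,
                           selectionConfig(nBootstrap = 25L), seed = 1L)
fit$trainC; fit$testC
fit$reliabilityTest$icc
```

This run selects a two-feature signature
(`original_firstorder_90Percentile`,
`original_shape_Maximum2DDiameterSlice`) and prints

```
[1] 0.8297872
[1] 0.8888889
ICC(1,1) = 0.917 (95% CI 0.722-0.987), n = 6 subjects x 3 raters: excellent reliability
```

i.e. a training C-index of 0.83, a test C-index of 0.89, and a model
reliability ICC of 0.92 under these (deliberately mild) perturbations.
Numbers vary with the seed and perturbation magnitudes; stronger
perturbations and fragile features push the ICC down, and screening features
at ICC > 0.75 (`screenMinIcc = 0.75`) raises it again — that direction is
asserted by the test suite.

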