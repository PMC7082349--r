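---
title: "Methods: a 3D radiomics signature pipeline for glioma-related epilepsy type"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 3D radiomics signature pipeline for glioma-related epilepsy type}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiradiomics)
```

## Problem and scope

Low-grade gliomas frequently cause epilepsy whose presentation —
generalized or focal — guides antiepileptic therapy. This package
implements a complete radiomics pathway from a T2-like 3D volume plus a
binary tumor mask to a per-patient probability of generalized epilepsy:
feature extraction (734 features), train-cohort feature selection, a
LASSO-logistic signature, and discrimination/calibration/utility
evaluation with a clinical nomogram. Because no patient cohort ships with
the package, a synthetic phantom generator provides a fully stated world
in which every stage can be tested end to end.

## The feature catalogue

The catalogue is fixed in a versioned registry (`feature_registry()`,
serializable with `write_feature_registry()`); the registry, not any
external document, is the authoritative definition of the 734 names and
their order.

* **Location (6).** Displacement of the unweighted ROI centroid from the
  anterior commissure, reported as polar coordinates and three distance
  norms. $r$ and the Euclidean distance coincide by definition; both are
  kept because the printed inventory lists six location features.
  $\theta$ is measured from the superior (+z) axis in $[0, \pi]$, $\Phi$
  from +x in the axial plane in $(-\pi, \pi]$; both are defined as 0 at
  zero displacement.
* **First-order (17).** Moments use population ($n$) denominators and
  kurtosis is non-excess (a normal scores 3); entropy (bits) and
  uniformity are computed on the same 32-level equal-width discretization
  as the texture matrices, so a constant ROI has entropy 0 and
  uniformity 1. Percentiles use the type-7 quantile.
* **Shape (8).** Two surface estimators exist. The default `"mesh"` route
  zero-pads the mask, smooths it lightly (separable 1-2-1 kernel, two
  passes, $\sigma \approx 1$ voxel) and triangulates the 0.5 level set by
  marching tetrahedra with interpolated edge crossings; area **and**
  enclosed volume are taken from the same closed mesh, so sphericity of a
  digital ball converges to 1 from below (measured 0.994 at radius 10
  voxels). The `"voxel"` route counts exposed voxel faces and voxel
  volumes, which is exact for box-like shapes (a unit voxel scores area 6)
  but overestimates smooth surfaces by up to 50%. The feature vector uses
  the mesh route; the voxel route is kept because exact face counts are
  the natural oracle for box fixtures.
* **Texture (26 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM).** Built on
  within-ROI intensities quantized to 32 equal-width levels (recomputed
  per image and sub-band, making all texture features invariant to
  intensity shifts). GLCM and GLRLM use the 13 unique distance-1
  directions and average features over directions; GLCM matrices are
  symmetrized and normalized per direction, and directions without a
  single valid pair are skipped in the average. GLSZM zones and NGTDM
  neighborhoods use 26-connectivity. For a single-level ROI the
  correlation-type GLCM features (correlation, both informational
  measures, the maximal correlation coefficient) are defined as 0 rather
  than propagating NaN into selection. NGTDM coarseness of a perfectly
  homogeneous ROI is capped at $10^6$.
* **Wavelet (640).** A one-level separable 3D transform with the
  orthonormal 6-tap Coiflet-1 pair, periodized (circular) boundary
  handling, odd axes padded by replicating the final slice. Each of the 8
  sub-bands is reconstructed onto the original grid by inverting the
  transform with the other bands zeroed; because the transform is
  orthonormal the 8 band images sum to the input exactly, and one mask
  serves all nine images. The 80 intensity-based features are recomputed
  per band: $8 \times 80 = 640$.

Anisotropic voxels are used as-is: location and shape work in physical
mm, texture offsets in voxel steps, matching a pipeline that reports no
resampling.

## Selection and the signature

Normalization is z-scoring with training-cohort means and standard
deviations only; train-constant features are excluded and counted.
Screening keeps a feature when the two-sided Pearson (point-biserial)
test against the binary label gives $p < 0.05$ **and** its rank AUC,
oriented as $\max(\text{AUC}, 1-\text{AUC})$, exceeds 0.6. The LASSO
penalty grid is 100 log-spaced values on $[10^{-4}\lambda_{max},
\lambda_{max}]$; for every $\lambda$ the leave-one-out misclassification
error at probability cut-off 0.5 is computed, the minimizer wins and ties
break toward the larger (sparser) $\lambda$. The signature is the
intercept-free linear weighting of the selected normalized features; the
logistic intercept is retained internally solely for probability
outputs, so signature values straddle 0 on z-scored features. `glmnet`
performs the penalized fits (it is the canonical implementation of this
estimator); the grid construction, LOOCV loop, tie rule and signature
arithmetic are this package's, and the $\lambda \to 0$ limit is tested
against an unpenalized `glm()` oracle.

Validation-cohort normalization reuses the training parameters (standard
practice; the alternative of re-estimating on validation data is not
implemented).

## Evaluation and the nomogram

* **Discrimination.** Rank AUC with midrank ties; 95% CI from the DeLong
  placement variance, clipped to $[0,1]$; accuracy/sensitivity/
  specificity at probability 0.5 (configurable).
* **Calibration.** Hosmer–Lemeshow on 10 equal-count risk bins, merging
  degenerate bins with a neighbor. The degrees of freedom depend on
  provenance: bins $-$ 2 when the probabilities come from a model fitted
  on the same data (the canonical setup, and the pipeline default), bins
  $-$ 0 when the probabilities are external truth — with known
  probabilities the bins $-$ 2 null rejects ~13% at nominal 5%, so the
  type-I property test uses `estimated_params = 0`.
* **Clinical utility.** Net benefit
  $TP/N - (FP/N)\,p_t/(1-p_t)$ on the grid $p_t \in \{0.01, \dots,
  0.99\}$, against treat-all and treat-none.
* **Multivariable model.** Backward elimination from
  {signature, age, gender, histopathology} under AIC with a fixed,
  deterministic candidate order; separation (|coefficient| > 15) aborts
  with advice. Following the published design the nomogram is fitted on
  the pooled cohort; the report flags that the signature term is
  optimistic there because selection saw the training half.
* **Nomogram.** Per predictor, the effect $\beta x$ over its observed
  range maps to 0–100 points, the widest effect spanning exactly 100;
  constant predictors fold into the baseline. Total points map to
  probability through the logistic form, making the points path and the
  direct evaluation identical by construction (tested at $10^{-6}$ over
  1000 patients).
* **Cohort table.** Age and signature by Student's independent-samples
  t-test (identical constant groups give $t = 0, p = 1$; distinct
  constant groups $p = 0$), gender and histopathology by two-sided
  Fisher's exact test, with $p = 1$ by convention for tables with an
  empty margin.

## The synthetic world

`synthetic_config()` states the emulated cohort once: 205 patients, 67.8%
generalized, 64×64×32 grids with 2×2×4 mm voxels, ellipsoidal tumors with
base radius 6–14 mm and per-axis anisotropy 0.75–1.25, intensity 100
inside versus background 20, multiplicative correlated Gaussian texture
(`exp(h·G)` with smoothed-noise field G and heterogeneity h in
[0.05, 0.6]), additive Gaussian noise (sd 2) applied last, AC fixed at
the grid's physical center (overridable), evenly spaced strictly
increasing surgery dates, and all randomness flowing from one master
seed through fixed per-patient substreams. The planted label effect acts
on the Chebyshev AC–centroid distance and the heterogeneity parameter
through a logistic model on standardized covariates whose intercept is
solved so the mean probability equals the prevalence.

Effect sizes are never hand-tuned: `calibrate_logistic_effect()` solves,
by deterministic quadrature, for the logistic slope whose induced
class-conditional distributions of a standard-normal score have a
requested population AUC (default 0.85, the scale of the published
signature discrimination).

`simulate_feature_cohort()` exercises the selection/evaluation stages at
full cohort size without image synthesis. Its four planted features share
a common latent factor with loading 0.7 (pairwise correlation ≈ 0.49,
per-feature population AUC ≈ 0.79, planted-score AUC exactly the 0.85
target). The loading matters: with independent equal-weight features the
same combined AUC forces each feature's own AUC down to ≈ 0.64, and the
p<0.05 ∧ AUC>0.6 screen then removes two or more planted features in a
large fraction of 102-patient training cohorts, so no recovery test
could both respect the combined effect size and expect reliable
selection. Correlated within-signature features are also what real
radiomic panels look like. The generator does **not** emulate MRI
physics, bias fields, multi-sequence acquisition, or realistic tumor
size/location distributions (unreported for the source cohort); a green
recovery test therefore establishes that the pipeline recovers a planted
monotone effect of the stated size at the stated sample size — not
clinical performance.

## Numerical choices and degenerate inputs

* Quantization bins are half-open with the ROI maximum assigned to the
  top level; a constant ROI maps to level 1.
* Empty masks, mismatched grids, non-finite features, one-class training
  labels, single-patient normalization and sub-`n_bins` calibration
  cohorts raise errors naming the study or feature; they are never
  silently repaired.
* A tumor radius that cannot fit the grid is a sizing error at phantom
  generation.
* NIfTI-1 I/O is a minimal single-file implementation (RAS+, sform,
  float32/uint8, gzip) written for this package because no NIfTI reader
  is available in the supported dependency set; it round-trips its own
  output and is not a general-purpose reader.
* The ICC gate uses the two-way random, absolute-agreement, single-measure
  ICC(2,1) on per-rater ROI volume series (the minimal segmentation
  summary; a per-feature series can be supplied instead). Agreement above
  0.8 triggers a seeded uniform rater choice per patient; otherwise the
  run halts with a classed error carrying the series.

## Known limitations

* Texture features are computed in voxel (not physical) offsets, so
  strongly anisotropic grids mix scales across directions — consistent
  with a no-resampling pipeline, but worth remembering when comparing
  across protocols.
* The LOOCV misclassification criterion is a coarse (0/1) loss; its error
  curve is flat over wide $\lambda$ ranges and selection can admit a few
  noise features at realistic effect sizes (visible in the README worked
  example).
* The mesh surface estimator smooths before triangulating; areas of
  deliberately spiky masks are biased low at the $\sigma^2 \times$
  curvature scale.
* The published patient-level results (training/validation AUC 0.859 /
  0.839, $\lambda^* = 0.067$, per-feature statistics) depend on an
  unavailable cohort and are treated as format references only; nothing
  in the test suite asserts them beyond the printed coefficient
  arithmetic of the published four-feature signature.
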