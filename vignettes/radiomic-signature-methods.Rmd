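---
title: "Methods: a CT-radiomics prognostic signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a CT-radiomics prognostic signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients with recurrent or metastatic head-and-neck squamous cell carcinoma
treated with immune checkpoint inhibitors split into a group with durable
benefit and a group that dies early; baseline clinical variables separate
the two poorly. `radsig` implements a complete CT-radiomics workflow for
that setting: from a contrast-enhanced CT volume and a segmentation of the
patient's largest lesion it derives a continuous risk score for the binary
endpoint *overall survival at 10 months*, dichotomised into high-risk (HR)
and low-risk (LR) calls, and compares that score against the clinical
baseline classifiers a tumour board would reach for (lesion volume, lesion
and organ counts, performance status, metastatic status).

Because the imaging data such models are built on cannot be redistributed,
the package ships a synthetic-cohort generator that emulates the
statistical structure the analysis assumes. Every stage of the pipeline is
exercised and validated on those synthetic cohorts.

## Pipeline

The stages, in training order, are:

1. **Preprocessing.** A 3D Gaussian filter (3×3×3 voxel kernel, σ = 0.5
   voxel, weights normalised to sum to one, mirror padding) denoises the
   volume; image and mask are then resampled to 2 mm isotropic spacing —
   cubic B-spline interpolation for intensities (exact interpolation via
   the recursive prefilter), nearest neighbour for the mask. Denoising
   precedes resampling. Nearest-neighbour mask interpolation was chosen
   over thresholded-linear because it fabricates no boundary voxels; on
   lesions at least 10 voxels across it preserves mask volume to within
   10%.

2. **Feature extraction: 536 features.** 14 shape features from the mask;
   18 first-order, 24 grey-level co-occurrence (GLCM) and 16 grey-level
   run-length (GLRLM) features from the original image; and the same 58
   intensity/texture features from each of 8 sub-bands of a one-level
   undecimated separable 3D wavelet decomposition (8 × 58 = 464).
   Intensities are discretised with a fixed bin width of 0.5 HU anchored at
   the ROI minimum (`level = 1 + floor((I − min)/w)`); each wavelet band is
   rediscretised on its own range, since the sub-band values live on
   different scales. Texture matrices use distance 1, the 13 unique 3D
   directions, symmetric accumulation, and features are computed per
   direction and averaged — which makes them invariant under 90°
   rotations of isotropic volumes, a property the test suite checks.

3. **Stability screening.** Features are recomputed with the mask
   translated by 10% of its bounding-box extent along each of ±x, ±y, ±z
   (seven measurements including the original) and screened by a one-way
   random-effects intraclass correlation, ICC(1,1) ≥ 0.75. The one-way
   form treats perturbed segmentations as exchangeable draws rather than
   fixed raters, which matches how the perturbations are generated; the
   number and geometry of translations are configuration knobs. Stability
   is computed on raw feature values — the ICC is location- and
   scale-invariant, so its order relative to Z-scoring is immaterial.

4. **Signature training.** Z-score normalisation (means and SDs frozen
   from the training set), redundancy pruning (for every pair with
   |Spearman ρ| > 0.85, visited in decreasing |ρ| order, the member with
   the higher mean absolute correlation to the remaining features is
   dropped; exact ties drop the lexicographically later name, making the
   outcome deterministic), a univariate filter keeping features with
   orientation-corrected rank-sum AUC > 0.7, SMOTE balancing of the
   training classes, LASSO (L1-penalised logistic regression, λ maximising
   mean cross-validated AUC over 5 stratified folds on a 50-point
   log-spaced grid), and a cubic-kernel SVM
   (K(u,v) = (γ u·v + r)³, degree 3, C = 1, r = 0,
   γ = 1/(n features · var), all configurable) whose continuous decision
   value is the signature score. The classification threshold is the ROC
   operating point of the training scores closest (Euclidean distance) to
   the ideal corner (sensitivity 1, false-positive rate 0), ties broken
   toward higher specificity.

5. **Frozen application and evaluation.** Test patients are normalised
   with the training parameters, scored with the frozen SVM and
   thresholded; no statistic of the test set influences any transformation
   (the test suite asserts the fitted model is bitwise invariant to
   corrupting test features and labels). Reported metrics: confusion
   counts, accuracy / sensitivity / specificity with 95% Wilson score
   intervals, trapezoidal ROC AUC (identical to the rank-sum statistic
   with half credit for ties) with a stratified-bootstrap interval
   (2000 draws, seeded), per-variable clinical baselines, and the Spearman
   correlation between signature and lesion volume with the t-based
   two-sided p-value.

### Design choices in the open

* **SMOTE placement.** Synthetic minority samples are created *after* the
  stability/redundancy/AUC selection and only for the LASSO and SVM fits.
  They never enter the ICC, the pruning, the per-feature AUC filter, or
  the threshold selection (which uses the original training patients'
  scores) — interpolated pseudo-patients should inform the classifier, not
  the feature-screening statistics.
* **AUC orientation.** The univariate filter scores a feature by
  max(AUC, 1 − AUC): a feature that orders the classes perfectly in either
  direction is maximally informative. The same logic drives the
  clinical-baseline evaluation, where a variable with raw AUC < 0.5 has
  its thresholding direction inverted before the operating point is
  chosen.
* **Wilson intervals.** The binomial intervals are Wilson score intervals;
  the package reproduces a published table of intervals on 5/12/17-patient
  denominators at two decimals with this method (Clopper–Pearson does
  not), which is why it is the package default.
* **GLCM roster.** The 24 co-occurrence features include the maximal
  correlation coefficient, computed as the spectral radius of the deflated
  symmetrised transition matrix by a fixed-step Lanczos recursion
  (deterministic start vector, ≤ 10 steps, exact for small matrices)
  rather than a dense O(N³) eigendecomposition; the identity
  HXY1 = HXY2 = HX + HY is used analytically in the information-measure
  features. Texture matrices are accumulated sparsely, so hundreds of grey
  levels (a consequence of the 0.5 HU bin width) stay memory-safe.
* **Surface mesh.** Shape surface area and mesh volume come from a
  marching-tetrahedra triangulation, at iso-level 0.5 with linear edge
  interpolation, of the *mollified* mask (binary indicator smoothed with a
  σ = 0.8 voxel Gaussian; tiny masks that the mollifier pushes below the
  iso level fall back to the binary indicator). The mollification removes
  the voxelisation staircase: a digital ball of radius 8 voxels measures
  sphericity ≈ 0.99 versus ≈ 0.79 for a midpoint mesh on the raw binary
  grid.
* **Degenerate inputs.** A constant ROI discretises to a single level and
  is flagged; contrast-type GLCM features are then 0 and correlation-type
  features take their degenerate limits. Zero-variance features are
  dropped before normalisation (logged). A zero-variance ICC matrix
  returns 1 with a degeneracy flag. Single-valued score vectors yield a
  midpoint threshold with a warning.
* **Fallbacks that keep null runs defined.** On a cohort with no planted
  signal the strict AUC > 0.7 filter is empty for a non-trivial fraction
  of seeds, and the CV-optimal λ can zero out every coefficient. The
  standalone operations keep their error contracts, but `fit_signature()`
  (by default) falls back to the single best-AUC feature when the filter
  is empty, restricts the λ choice to grid points with a non-empty active
  set, and skips the penalised fit altogether when only one candidate
  feature remains. All fallbacks are deterministic and logged; without
  them a "no-signal" calibration study would abort instead of reporting
  chance performance.

## The synthetic cohort generator

`generate_cohort()` draws, per patient: a binary 10-month survival label
(event rate 0.3 by default, matching a test-set prevalence of 5/17); a
lobulated ellipsoidal lesion — the largest-lesion surrogate — whose mean
diameter is 20 mm for long survivors and `volume_effect` × 20 mm for short
survivors (patient-level lognormal scatter, per-axis jitter, three surface
lobes); and intra-lesional texture as a stationary Gaussian random field
(white noise smoothed to a 3 mm correlation length) with contrast 15 HU,
scaled by `heterogeneity_effect` for short survivors. The background is
0 HU with 10 HU white noise; lesions sit on a 64³ grid at 1×1×3 mm
spacing, so isotropic resampling is genuinely exercised. Labels are drawn
first and images are conditioned on them. Clinical covariates (lesion
count, affected organs ≤ lesions, performance status 0/1/2 at 32/65/3%,
~44% non-metastatic) follow marginal distributions typical of
recurrent/metastatic head-and-neck cohorts and are independent of the
label, so only the imaging carries signal. The whole cohort is a pure
function of its configuration, and the first ⌊0.8 n⌋ patients form the
training set — a chronological split surrogate.

Effect sizes are free parameters, not estimates: no public cohort exists
to calibrate them against. What the generator does *not* emulate: scanner
heterogeneity (25 scanner models in a real multicentre trial),
inter-observer segmentation variability, multi-lesion anatomy, partial
volume effects at air/bone interfaces, or any dependence of clinical
covariates on outcome. Passing tests therefore demonstrate that the
pipeline recovers a planted imaging signal and stays at chance without
one — not that the signature generalises to real CT data.

## Calibration and recovery studies

Three whole-pipeline studies run in the test suite, sharing cached runs:

* **Null calibration** — no planted effect (volume and heterogeneity
  ratios both 1): mean test AUC over 20 seeds must lie in [0.35, 0.65].
* **Signal recovery** — heterogeneity ratio 2.5 (volume ratio at its
  default 1.3) at 200 training / 50 test patients: mean test AUC over 20
  seeds must reach 0.8.
* **Monotonicity** — mean test AUC is non-decreasing in the heterogeneity
  ratio over {1.0, 1.5, 2.5} at fixed cohort size, with the volume ratio
  held at 1 so heterogeneity is the only planted signal (small slack for
  the sampling error of 20-seed means).

The null and monotonicity studies use cohorts of 60 patients (48/12
split); the signal-recovery study uses 200/50. Seeds whose test split
contains a single class are skipped and replaced by the next seed in the
deterministic sequence, because a test AUC is undefined there. These sizes
are the package's choice of problem scale; at 12–50 test patients and 20
seeds the standard error of a mean null AUC is ≈ 0.04, comfortably inside
the calibration band.

For speed, cohort-level extraction preprocesses a 16 mm-padded
neighbourhood of the lesion rather than the full field of view; the
recursive B-spline prefilter's boundary influence decays geometrically
(pole ≈ −0.27), so intensities within the ROI are unchanged to well below
the discretisation bin width.

## Numerical notes

* Separable convolutions use half-sample reflection padding; the B-spline
  prefilter and interpolation use whole-sample mirroring (the boundary
  model under which the recursive prefilter is exact). Resampling maps
  output voxel centres to input coordinates `u = (i + 0.5)·t/s − 0.5` and
  uses `round(n·s/t)` output voxels, preserving physical extent to within
  one voxel; an already-isotropic grid is reproduced to machine precision.
* The wavelet family is Coiflet-1 (Haar available); band labels give the
  filter applied along x, y, z, e.g. HLH = high-pass x, low-pass y,
  high-pass z.
* Kurtosis is non-excess (a normal distribution scores 3); entropy and
  uniformity are computed on the discretised levels; percentiles use
  linear interpolation.
* All randomness (cohort, SMOTE, CV folds, bootstrap) derives from one
  master seed through fixed arithmetic, so a configuration determines its
  report byte-for-byte; model serialisation stores full floating-point
  precision and reloaded models reproduce scores to < 1e−12.

## Known limitations

The redundancy-pruning outcome depends on the pair-visiting order (the
deterministic decreasing-|ρ| order is a convention, not an optimum). The
Lanczos estimate of the maximal correlation coefficient is a lower bound
when the spectrum is nearly degenerate — deterministic, but not to full
precision for large level counts. The bootstrap AUC interval is a
percentile interval and degenerates on tiny, well-separated test sets.
The generator plants signal through size and texture contrast only; a
pipeline that passes these studies could still fail on signals carried by
features the generator cannot express.
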