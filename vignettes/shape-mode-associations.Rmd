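---
title: "Methods: hip shape modes and early-osteoarthritis outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hip shape modes and early-osteoarthritis outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hipshapes)
```

This vignette documents the statistical model behind `hipshapes`, the
assumptions each stage makes, the parameters of the synthetic cohort
generator, and the numerical choices that matter for reproducibility. It
is a methods document: every quantitative claim here is either a design
parameter or something the test suite verifies; nothing is an empirical
finding.

## The scientific question

Proximal femur shape is a suspected risk factor for early hip
osteoarthritis. The analysis implemented here takes a cohort of
participants — two hips each — with (a) 82 anatomical landmarks outlining
the proximal femur on an anteroposterior radiograph and (b) MRI-based
SHOMRI (Scoring Hip Osteoarthritis with MRI) gradings of cartilage and
labrum, and asks: *which independent modes of shape variation are
associated with the presence of cartilage defects or labral tears?*

The pipeline has four statistical stages:

1. **Alignment** — generalized Procrustes analysis (GPA) removes
   position, orientation, and size, leaving shape.
2. **Decomposition** — principal component analysis (PCA) of the aligned
   coordinates yields orthogonal *shape modes*; modes explaining at least
   1.00% of total shape variance are retained.
3. **Outcome definition** — ordinal SHOMRI grades are dichotomized:
   a *cartilage defect* is any of the 10 cartilage subregion grades
   ≥ 1; a *labral tear* is any of the 4 labral subregion grades ≥ 2.
4. **Association** — each retained mode score is regressed on each
   binary outcome with a GEE logistic model, clustered on participant,
   with robust (sandwich) standard errors. Models are fitted crude and
   adjusted for age, BMI, and symptomatic status. Effects are reported
   as odds ratios per SD of mode score.

Analyses are stratified by sex throughout, because male and female
proximal femora differ systematically in both scale and shape; pooling
would make the leading "modes" sex-discriminators rather than
within-population variation.

## Alignment: generalized Procrustes analysis

Each hip is an 82×2 landmark matrix. `generalized_procrustes()` performs
*full* Procrustes alignment:

- every configuration is centered and scaled to unit centroid size
  (the root-mean-square distance of landmarks from their centroid);
- each is rotated onto the current consensus by the orthogonal
  Procrustes solution (SVD of the 2×2 cross-covariance, determinant
  constrained to +1 so reflections are never introduced);
- the consensus is the coordinate-wise mean, renormalized to unit size;
- iteration continues until the residual sum of squares changes by less
  than `tol = 1e-8`, with the first shape as the initial consensus and a
  final rotation pass after convergence so every shape is optimally
  rotated onto the *final* consensus.

Left hips are reflected into the right-hip frame (`mirror_left()`, an
x-negation) *before* alignment; this is what makes the determinant-+1
constraint sound, and it treats left/right asymmetry as noise, which is
an explicit modeling choice rather than a mathematical necessity.

No tangent-space projection is applied after alignment. For the
dispersions involved here (landmark noise ≪ object size) the curvature
of shape space is negligible relative to sampling noise, and operating
on aligned coordinates keeps every downstream quantity interpretable in
the original units.

## Decomposition: PCA shape modes

`fit_shape_model()` runs `prcomp` (no rescaling of coordinates — all
landmarks share units) on the aligned, flattened configurations. A few
conventions remove arbitrariness:

- the number of retained components is capped at
  `min(n − 1, 2k − 4)` where `k = 82` landmarks: centering costs one
  degree of freedom and the similarity group (2 translations, 1
  rotation, 1 scale) costs four;
- each mode's sign is fixed so its largest-magnitude loading is
  positive (PCA signs are otherwise arbitrary and would make results
  machine-dependent);
- scores are standardized by their sample SD (n − 1 denominator), so
  regression coefficients are per-SD log odds ratios;
- `select_modes()` keeps modes with variance fraction ≥ 1.00%,
  computed from unrounded fractions (the printed variance table rounds
  *after* selection).

## Outcomes and clinical filters

`classify_symptomatic_status()` implements hip-level status:
*symptomatic* requires pain for more than 6 months **and** a positive
FADIR (flexion–adduction–internal-rotation) test; the contralateral hip
of a symptomatic participant is *other*; all remaining hips are
*asymptomatic*. Hips with Kellgren–Lawrence grade > 0 are excluded
per-hip (`exclude_kl()`): the target of inference is *early* (pre-
radiographic) degeneration.

Dichotomization (`derive_outcomes()`) uses different grade cutoffs for
the two outcomes deliberately: SHOMRI cartilage grade 1 already denotes
a partial-thickness defect, whereas labral grade 1 denotes signal
abnormality only — a tear begins at grade 2.

## Association: GEE logistic with sandwich variance

The two hips of a participant are correlated. `fit_gee_logistic()`
implements the Liang–Zeger estimating equations for a logit link:

- Fisher scoring from an ordinary IRLS start;
- exchangeable working correlation by default (one correlation for the
  hip pair — the natural structure for bilateral organs), with
  independence available; the moment estimator of the exchangeable
  correlation is clipped to ±0.99 with a warning if degenerate;
- robust variance is the sandwich `B⁻¹ M B⁻¹`; an optional
  Mancl–DeRouen small-sample correction inflates residuals by
  `(I − H)⁻¹` per cluster.

Consistency of the point estimates does not depend on the working
correlation being right; only efficiency does. The sandwich variance is
what makes the per-mode Wald tests honest under misspecification — the
test suite verifies coverage of the robust CI (≈95%) and type-I error
(≈5%) by simulation, and checks that GEE with independence working
correlation on singleton clusters reproduces ordinary logistic
regression to 8 decimals.

Reporting conventions: `or_per_sd()` gives OR = exp(β) with the robust
Wald 95% CI; `or_at_k_sd()` compounds a per-SD odds ratio to a k-SD
contrast as OR^k (e.g. a per-SD OR of 0.75 is 0.75⁻³ ≈ 2.37 at −3 SD);
`bonferroni_alpha()` is 0.05 divided by the number of tested modes,
reported to 4 decimals. Multiplicity is handled across modes within an
outcome; crude and adjusted models are not additionally corrected.

## The synthetic cohort generator

No imaging data ship with the package; `simulate_cohort()` produces a
cohort with *known* ground truth so every pipeline stage can be
validated end to end. What it emulates:

- **Template geometry.** An 82-point right proximal femur outline built
  from circular arcs (femoral head, acetabular rim) and Bézier segments
  (neck and shaft), with sex-specific head radius (25 mm male, 22 mm
  female). Consecutive landmarks are ≤ 6 mm apart, so "smooth
  deformation" is meaningful.
- **Shape variation.** `n_true_modes = 15` orthonormal deformation
  fields, built by smoothing white noise along the outline
  (moving-average window 7) and Gram–Schmidt-orthogonalizing against
  the 4-dimensional similarity subspace (translations, rotation, scale)
  — so true shape variation is, by construction, invisible to GPA's
  nuisance removal. Mode variances decay as `λ_j ∝ j^−1.3`, scaled so
  mode 1 has ≈ 2 mm RMS amplitude.
- **Nuisance.** Each configuration receives a random similarity
  transform (translation, rotation, scale) plus isotropic landmark
  noise (SD 0.5 mm); left hips are mirrored. GPA must undo all of this.
- **Outcomes.** Binary outcomes follow a logistic model in the true
  mode scores (defaults: protective and deleterious effects on modes 1,
  12, 15 for cartilage; mode 12 for labral tears), plus age, BMI, and
  symptomatic-status effects and a participant-level random intercept
  (SD 0.5 on the logit scale) inducing within-pair correlation. SHOMRI
  subregion grades are generated so they dichotomize back *exactly* to
  the latent binary outcome.
- **Demographics.** 229 participants with the study-like sex split
  (178 male), truncated-normal age and BMI per sex, ≈ 4% of hips with
  KL > 0, and a symptomatic/other/asymptomatic mix of ≈ 63/16/21%.

What it does **not** emulate: segmentation error structure (noise is
iid isotropic), correlated grader behavior across SHOMRI subregions,
missing data, or any real anatomy beyond the template's plausible
outline. Conclusions about the *method* transfer; conclusions about
hips do not.

All generator parameters are arguments of `generator_config()` and are
documented there with units; everything downstream of a config and a
seed is deterministic, and `run_pipeline()` reruns are byte-identical.

## Numerical choices worth knowing

- Convergence: GPA `tol = 1e-8` on RSS; GEE `tol = 1e-10` on the
  coefficient max-change, 50 iteration cap with a warning.
- Landmark files round-trip through text at `%.12g`, preserving
  doubles to ~1e-12 relative error.
- Degeneracies fail loudly: coincident landmarks (zero centroid size),
  zero cross-covariance in the rotation solve, perfect separation and
  rank deficiency in the logistic fit all raise distinct errors rather
  than returning garbage.
- Problem sizes: the shipped analysis uses 229 participants; the
  simulation-based calibration tests use 150-participant cohorts with
  800 (coverage) and 2000 (type-I error) replicates.

## Limitations

The 1.00% variance threshold, the exchangeable working correlation, the
6-month/FADIR symptomatic rule, and the grade cutoffs are inherited
conventions, not optimized choices; all are single arguments if you
want to vary them. The per-SD odds ratio compounding rule OR^k assumes
linearity of the log odds in the mode score across the whole ±3 SD
range, which is an extrapolation at the extremes. And the synthetic
generator can validate correctness and calibration of the machinery,
but not the anatomical validity of any particular finding.
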