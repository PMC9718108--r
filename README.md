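# hipshapes

Statistical shape modeling of hip morphology with cluster-robust outcome
association.

## The scientific problem

Subtle variation in proximal femur shape — cam-like asphericity of the
head–neck junction, neck-shaft geometry, head size relative to the
acetabulum — is a suspected driver of early hip osteoarthritis, before
anything is visible on a radiographic severity scale. Studying this
requires (a) a way to quantify shape that does not depend on where the
hip sits in the image, how it is rotated, or how large the patient is,
and (b) an association analysis that respects the fact that each
participant contributes **two** correlated hips.

`hipshapes` implements that analysis end to end for cohorts of 82-point
landmark outlines of the proximal femur on anteroposterior radiographs,
paired with MRI-based SHOMRI (Scoring Hip Osteoarthritis with MRI)
gradings:

1. **Generalized Procrustes analysis (GPA)** — full alignment (center,
   unit centroid size, optimal rotation with no reflections; left hips
   mirrored into the right-hip frame first) so that only *shape* remains.
2. **PCA shape modes** — orthogonal modes of the aligned coordinates;
   modes explaining ≥ 1.00% of shape variance are retained, and scores
   are standardized so effects are "per SD of mode score".
3. **Outcome definition** — SHOMRI grades dichotomized: *cartilage
   defect* = any of 10 subregion grades ≥ 1; *labral tear* = any of 4
   subregion grades ≥ 2. Hips with Kellgren–Lawrence grade > 0 are
   excluded (the target is pre-radiographic disease).
4. **GEE logistic association** — for each retained mode and each
   outcome, a logistic model estimated by generalized estimating
   equations (exchangeable working correlation over the hip pair,
   Liang–Zeger sandwich variance), crude and adjusted for age, BMI, and
   symptomatic status; reported as odds ratios per SD with robust 95%
   CIs, at nominal and Bonferroni significance levels.

The intended audience is musculoskeletal imaging and epidemiology
groups who want a tested, scriptable reference implementation of this
pipeline — plus a synthetic cohort generator with known ground truth
(`simulate_cohort()`), so every stage can be validated without any
patient data.

## The model in brief

Each hip is a configuration `X ∈ R^(82×2)`. GPA minimizes
`Σᵢ ‖βᵢ Xᵢ Γᵢ + 1γᵢᵀ − M‖²` over scales βᵢ, rotations Γᵢ (det +1),
translations γᵢ, and the consensus M. PCA of the aligned, flattened
configurations gives modes `v₁, v₂, …` with standardized scores
`z_ij`. For outcome `Y` (binary) the per-mode model is

    logit P(Y_ij = 1) = β₀ + β₁ z_ij + (covariates),

estimated by GEE with clusters = participants, so that
`exp(β₁)` is the odds ratio per SD of the mode score and its Wald CI
uses the sandwich variance `B⁻¹MB⁻¹`. A per-SD odds ratio `r`
compounds multiplicatively: the odds ratio at a k-SD contrast is `r^k`
(`or_at_k_sd()`), e.g. `0.75⁻³ ≈ 2.37`.

## Worked example

Simulate a small all-male cohort with known shape–outcome effects, run
the full pipeline on it, and scan modes against cartilage defects:

```r
library(hipshapes)

cfg <- generator_config(n_participants = 120, male_fraction = 1, seed = 7)
cohort <- simulate_cohort(cfg)
clinical <- derive_outcomes(exclude_kl(cohort$clinical)$retained)

# Mirror left hips, align, fit the shape model
keep <- paste0(clinical$participant_id, "_", clinical$side)
landmarks <- lapply(cohort$landmarks[keep], function(lm)
  if (lm$side == "left") mirror_left(lm) else lm)
gpa <- generalized_procrustes(landmarks)
model <- fit_shape_model(gpa, sex = "male")
modes <- select_modes(model)          # variance fraction >= 1.00%
head(variance_table(model), 3)
#>   mode pct_variance cum_pct_variance
#> 1    1         38.8             38.8
#> 2    2         17.1             55.9
#> 3    3          9.8             65.7

scan <- run_association_scan(
  scores = model$standardized_scores,
  outcomes = list(cartilage_defect = clinical$cartilage_defect_present),
  covariates = clinical[c("age", "bmi", "symptomatic_status")],
  cluster_ids = clinical$participant_id,
  selected_modes = modes
)
subset(scan, sig_05, select = c(mode, aor, aci_low, aci_high, ap))
#>    mode  aor aci_low aci_high     ap
#> 5     5 1.34    1.01     1.77 0.0425
#> 14   14 0.62    0.46     0.86 0.0036

or_at_k_sd(0.75, -3)   # per-SD OR 0.75 at a -3 SD contrast
#> [1] 2.37
```

The generator's ground truth for this configuration includes a
protective per-SD effect of 0.61 on its last true mode; fitted mode 14
— whose scores correlate most strongly (r ≈ 0.6) with that true mode,
mixed with its low-variance neighbours — picks the signal up as an aOR
of 0.62. With 120 participants, effects this size sit near the
detection limit — see `minimal_detectable_or()` for the power
calculation.

`run_pipeline()` wraps all of the above (per-sex, both outcomes) into a
single deterministic run that writes variance tables, association
tables, mode-shape landmark files at ±3 SD, and a manifest; reruns with
the same config are byte-identical.

## Repository layout

- `R/`, `tests/testthat/` — the package and its test suite (unit,
  property-based, oracle cross-checks, and simulation-based calibration
  of CI coverage and type-I error).
- `analysis/01_simulate_cohort.R` … `05_interpretation.R` — the
  narrative analysis workflow: thin, numbered drivers over the package
  that simulate the 229-participant cohort, fit per-sex shape models,
  summarize the cohort, run the association scans, and convert effect
  sizes; small result tables land in `results/`, bulky intermediates in
  `scratch/`.
- `vignettes/shape-mode-associations.Rmd` — the methods vignette:
  model, assumptions, generator parameters, numerical choices, and
  limitations.

## Reproducing results

`scripts/acceptance.R` recomputes the package's headline quantitative
claims from the installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It evaluates the per-SD odds-ratio compounding rule at the reported
effect sizes (per-SD ORs of 0.75 and 0.61 at −3 SD and −1 SD
contrasts). The broader claims — nuisance invariance of GPA, exact
eigenstructure recovery by the shape model, equivalence of GEE to
ordinary logistic regression under independence, 95% CI coverage and
5% type-I error of the robust tests, byte-identical pipeline reruns —
are recomputed by the test suite (`tests/testthat/test-acceptance.R`)
rather than the script, since they are distributional properties, not
single numbers.
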