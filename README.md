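# ichagree

Synthetic phantoms and agreement statistics for intracerebral haemorrhage
(ICH) volumetry.

## What this package is for

ICH volume is a key prognostic factor and a criterion for neurosurgical
treatment and trial eligibility, and it is measured by methods of very
different character: semi-automatic segmentation (the reference standard),
the bedside ABC/2 ellipsoid estimate, and fully automated segmentation
software. Validating agreement between such methods requires a specific
statistical pipeline — and the patient imaging behind published
method-comparison studies is rarely shareable. `ichagree` is for
biostatisticians and imaging methodologists who want that entire pipeline
as tested, reusable code, runnable end-to-end on synthetic cohorts with
realistic structure:

- **Phantom generation** — 3D haematoma masks on CT-like voxel grids:
  radially deformed ellipsoids (band-limited angular noise), attached
  intraventricular haemorrhage (IVH) components, distractor hyperdensities,
  axial reslicing to 1/3/5 mm, NIfTI export; cohort-level ground truth with
  lognormal volumes calibrated to a median of 26.0 mL (IQR 9.3–59.2), 50%
  IVH prevalence, 66% deep location.
- **Volumetry** — voxel-count reference; ABC/2 with Kothari 75%/25% slice
  weighting (`A·B·C/2`, `A` the largest axial diameter, `B` the largest
  perpendicular diameter on the same slice, `C` the weighted slice count ×
  thickness); a parametric automated-segmentation simulator with the
  documented failure modes (missed small haematomas via logistic detection
  in log-volume, IVH inclusion, partial segmentation, distractor inclusion,
  multiplicative noise); an ABC/2 reader-noise model.
- **Agreement statistics** — Bland–Altman limits of agreement
  `mean ± 1.96·SD` (absolute and percent), Kendall's τ heteroscedasticity
  screen (τ > 0.1), log transformation with back-transformed mean-dependent
  limits `slope·X`, `slope = 2(e^l−1)/(e^l+1)`; one-way random-effects ICC
  for unbalanced reader designs; paired t and Shapiro–Wilk tests; subgroup
  analyses (IVH, location, 40 mL); the ±10% clinical acceptability rule.
- **Sample size** — power and minimum n for limits-of-agreement studies
  (analytic integration cross-checked against a Monte-Carlo oracle).
- **Pipeline** — `run_study()` chains everything into a seed-reproducible
  JSON report with a shipped schema; CSV/NIfTI/YAML interfaces and a thin
  CLI (`inst/cli/ichagree.R`) with subcommands `simulate-cohort`,
  `measure`, `agree`, `sample-size`, `report`.

## A worked example

```r
library(ichagree)

# a 300-case synthetic study at the calibrated defaults
res <- run_study(study_config(seed = 1))

res$report$n_missed
#> [1] 52
res$report$icc_abc2$icc
#> [1] 0.9957190

acc <- res$report$acceptance[["auto_sim vs reference_voxel"]]
str(acc)
#> List of 4
#>  $ limit_pct : num 10
#>  $ loa_low   : num -59.8
#>  $ loa_high  : num 60.6
#>  $ acceptable: logi FALSE
```

Fifty-two of 300 cases are missed by the simulated automated segmenter
(detection 82.7%, concentrated among small haematomas: the median true
volume of missed cases is 5.0 mL against 35.9 mL for the complete cases),
the ABC/2 inter-observer ICC is ≈ 0.996, and the automated method's percent
limits of agreement (−59.8% to +60.6%) fail the ±10% clinical rule — while
an error-free model (`auto_seg_error_model(zeroed = TRUE)`) reproduces the
reference exactly and passes it.

Single pieces work standalone:

```r
ell <- make_ellipsoid_mask(c(30, 20, 10), c(0.5, 0.5, 0.5), c(132, 92, 52))
abc2_measure(ell, "full_extent")
#> <abc2_measurement> A=5.97 B=4.00 C=2.00 cm -> 23.88 mL (slice 26)
voxel_volume_mL(ell, 1)                # 25.11 (analytic: 25.13)
loa_sample_size(sample_size_config(mu_d = 0, sd_d = 2, delta = 5))
#> <sample_size_result> n = 108 (achieved power 0.804, target 0.80)
```

The methods vignette (`vignettes/ich-volumetry-agreement.Rmd`) documents
the phantom model, the estimator conventions, every calibrated default and
the design decisions behind them.

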