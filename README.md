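# dgmiron

Brain iron accumulates with age in the deep gray matter (DGM) — accumbens,
amygdala, caudate, globus pallidus, hippocampus, putamen, thalamus — and an
abnormal load there is linked to neurodegeneration. Two MRI proxies track it
*in vivo*: **QSM** (quantitative susceptibility mapping, the bulk magnetic
susceptibility χ of a voxel in ppb, inverted from the gradient-echo phase)
and **R2\*** (the apparent transverse relaxation rate 1/T2\* in s⁻¹, fitted
from the multi-echo magnitude decay).

`dgmiron` is an R implementation of the full analysis chain used to
establish normal-aging reference values for these proxies at 7 T, aimed at
researchers who want to validate, stress-test or reuse such a pipeline
without access to the original cohort:

* **Digital phantom + forward model** — bilateral ellipsoidal DGM structures
  with known χ and R2\*, and the 10-echo MGRE complex signal
  `M0·exp(−R2*·TE)·exp(i·2π·f·TE)` with the dipole field
  `f = γ̄B0·(D∗χ)`, `D(k) = 1/3 − (k·b̂)²/|k|²`.
* **QSM reconstruction** — Laplacian phase unwrapping, magnitude-weighted
  field fitting with a residual-based reliability mask, variable-radius
  spherical-mean-value (V-SHARP) background-field removal, thresholded
  k-space division (TKD) with point-spread amplitude correction, brain-mean
  referencing.
* **R2\* mapping** — weighted log-linear fit refined by nonlinear least
  squares.
* **ROI statistics** — the μ±2σ trimmed mean per subject/ROI/metric,
  inter-hemispheric Wilcoxon tests, bilateral averaging, volume/TIV
  correlations.
* **Cohort simulator + statistics** — subjects drawn from the published
  sex-stratified linear age models (slope, intercept, *and* slope SE, via
  the OLS identity `SE = σ/√Sxx`), demographics matched to the study
  (40 F / 37 M, age tertiles 54–62 / 62–69 / 69–78, ApoE ε4 and
  cardiovascular-risk rates); least-squares age regressions, Mann–Whitney
  group comparisons for six grouping parameters (16 pairwise comparisons ×
  7 ROIs = Bonferroni factor 112), median percent differences.

## Worked example

```r
library(dgmiron)

## cohort level: simulate 77 subjects from the published age models and
## refit the female putamen QSM regression
sim <- simulate_cohort(seed = 1)
putamen_f <- merge(
  subset(sim$roi, roi_name == "putamen" & metric == "qsm_ppb"),
  subset(sim$cohort, sex == "F")[, c("subject_id", "age")])
fit_age_regression(putamen_f$age, putamen_f$trimmed_mean)
#> Linear age model (n = 40): slope 0.861 +/- 0.301 per year, intercept -22.42 +/- 20.23, p = 0.0068

plan <- comparison_plan()
attr(plan, "n_pairs"); attr(plan, "n_tests")
#> [1] 16
#> [1] 112

cmp <- compare_groups(sim$roi, sim$cohort, plan)
subset(cmp, roi_name == "putamen" & metric == "qsm_ppb" & parameter == "age" &
       group_a == "54-62" & group_b == "69-78")[,
  c("median_a", "median_b", "percent_difference", "u_statistic", "p_raw", "p_bonferroni")]
#>  median_a median_b percent_difference u_statistic   p_raw p_bonferroni
#>      26.6     40.9               53.7         156 0.00157        0.176
```

The fitted slope (0.86 ± 0.30 ppb/year) is this one cohort draw's estimate
of the generating value 1.25 ppb/year — within two standard errors, as the
calibration intends; across 200 seeded cohorts the ensemble mean recovers it
to about 1%.
The group comparison reports the age-tertile medians, their percent
difference and the Mann–Whitney p-value before and after the ×112
correction.

```r
## imaging level: phantom -> MGRE signal at SNR 50 -> QSM + R2* -> trimmed ROI means
g <- acquisition_geometry(grid_shape = c(64, 64, 64), voxel_size = 1.2)
ph <- make_phantom(g)
series <- simulate_mgre(ph, forward_field(ph, g), g, snr = 50, seed = 1)
rec <- recon_qsm(series, ph$brain_mask, recon_config(reference = "none"))
roi_table(rec$qsm, ph$labels, ph$label_table, reliability = rec$qsm$mask)
```

merged across hemispheres and set against the phantom ground truth:

```
        roi_name trimmed_mean truth_ppb n_voxels_used
       accumbens        -8.06     -7.77           158
        amygdala       -22.62    -19.88           460
         caudate        37.74     37.64           572
 globus pallidus        89.41     87.56           277
     hippocampus       -13.68    -14.54           682
         putamen        32.79     32.98           977
        thalamus       -13.25    -13.01           995
```

A command-line front end over the same functions is installed at
`inst/cli/dgmiron.R` (subcommands `simulate-phantom`, `recon-qsm`,
`fit-r2star`, `extract-roi`, `simulate-cohort`, `analyze-cohort`,
`run-all`).

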