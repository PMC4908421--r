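# glycosurv

Prognostic analysis of the plasma IgG N-glycome in colorectal cancer (CRC)
cohorts, as a tested, reusable R pipeline.

The IgG glycome — resolved by HILIC-UPLC into 24 chromatographic peaks
(GP1–GP24) — modulates the antibody's inflammatory activity: loss of
galactose and sialic acid makes IgG pro-inflammatory, and bisecting GlcNAc
raises effector activity. `glycosurv` is for biostatisticians and
glycomics groups asking whether a single post-diagnosis glycome measurement
carries prognostic information beyond clinicopathological staging.

The pipeline covers:

* **Glycomics** — total-area normalisation (each peak divided by its
  chromatogram total), derived traits as peak-set ratios
  (G0ⁿ/G1ⁿ/G2ⁿ galactosylation, Fⁿ/FBⁿ fucosylation and bisection,
  FGS/(FG+FGS)-style sialylation ratios), a technical-replicate robustness
  filter (`100·Var(standards)/Var(cohort)`, traits strictly below 20%
  retained), and Blom rank-normal transforms for per-SD hazard ratios.
* **Survival** — Cox proportional-hazards association scans (crude;
  age/sex/stage-adjusted; fully adjusted), all-cause and CRC-specific
  mortality (other-cause deaths censored), whole-sample / stage-excluded /
  stage-stratified, Benjamini–Hochberg q-values per scan family,
  proportional-hazards and linearity diagnostics, Breslow baseline 5-year
  risks.
* **Discrimination** — Harrell's C, cumulative/dynamic time-dependent
  AUC(t) with Kaplan–Meier censoring weights, discrimination slopes and the
  IDI.
* **Selection** — bootstrap gradient-boosted Cox (stump) importance
  ranking, forward selection by likelihood-ratio test, and L1-penalised Cox
  validation-deviance comparison with clinical terms unpenalised.
* **Progression** — stage-wise "rapid progressor" labels (lower tertile of
  CRC-death times within stage), a 7-class classifier zoo under repeated
  stratified cross-validation with leakage-safe preprocessing, and the
  paired Wilcoxon signed-rank comparison of models with and without glycans
  (exact for up to 25 untied pairs).
* **Synthetic cohorts** — a generator with planted ground truth
  (logistic-normal 24-peak compositions with plate standards, clinical
  marginals and Weibull stage hazards at the published values) so every
  stage is testable without patient data.

## Worked example

```r
library(glycosurv)

sim <- simulate_cohort(generator_config(n_patients = 1229), seed = 1)
#> synthetic_cohort: 1229 patients, 584 deaths ( 444 CRC ), seed 1

tm <- filter_robust(compute_robustness(
  derive_traits(normalize_total_area(sim$peak_table))))
#> trait_matrix: 1229 cohort samples, 42 standard wells, 63 traits
#>   retained after robustness filter: 63

traits <- cohort_traits(tm, transform = "none")
scan <- association_scan(
  traits[, c("sample_id", "G0n", "G1n", "G2n", "FGS/(FG+FGS)", "FBn")],
  sim$cohort, model_spec("II"))
scan[order(scan$p), c("trait", "hr", "ci_lower", "ci_upper", "p", "q")]
#>         trait    hr ci_lower ci_upper        p        q
#>           G0n 1.238    1.137    1.348 9.53e-07 4.15e-06
#>           G2n 0.815    0.749    0.886 1.66e-06 4.15e-06
#>  FGS/(FG+FGS) 0.843    0.775    0.916 6.11e-05 1.02e-04
#>           G1n 0.883    0.810    0.961 4.22e-03 5.28e-03
#>           FBn 1.010    0.929    1.098 8.22e-01 8.22e-01
```

Hazard ratios are per rank-normal SD: agalactosylation (G0ⁿ up, HR 1.24) is
harmful, galactosylation and sialylation protective — the generator's
planted pro-inflammatory axis, recovered through the full
peaks → traits → QC → scan chain. FBⁿ sits off that axis and is null.

```r
rec <- sim$cohort; rec$stage <- factor(rec$stage)
f3 <- fit_cox(rec, c("age", "sex", "stage", "bmi", "crp_gt10"))
f2 <- fit_cox(rec, c("age", "sex", "stage"))
compare_discrimination(f3, f2, rec, horizon = 5)
#> Harrell's C (extended clinical): 0.72
#> AUC(5y): 0.78
#> IDI vs age/sex/stage: 0.023

label_rapid_progressors(sim$cohort, 4)
#> stage-4 rapid-progressor cutoff: 1.17 years (44 rapid of 141)
```

The clinical model discriminates at C ≈ 0.72 with a stage-4 rapid-progressor
cutoff near 1.2 years — the scale reported for cohorts of this design.

See `vignettes/igg-glycome-prognosis.Rmd` for the model assumptions,
generator calibration, numerical conventions and known limitations
(including the anticonservatism of the paired with/without-glycans
comparison).

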