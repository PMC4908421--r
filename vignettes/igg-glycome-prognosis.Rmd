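---
title: "Methods: IgG glycome prognostic analysis with glycosurv"
author: "glycosurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IgG glycome prognostic analysis with glycosurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Immunoglobulin G carries a biantennary N-glycan at Asn297 of each heavy
chain, resolved by hydrophilic-interaction UPLC into 24 chromatographic
peaks (GP1--GP24). The composition of this glycome modulates the antibody's
inflammatory behaviour: loss of galactose and sialic acid makes IgG
pro-inflammatory, while bisecting GlcNAc and absence of core fucose raise
antibody-dependent cytotoxicity. `glycosurv` implements a complete analysis
chain for asking whether this glycome, measured once after colorectal-cancer
diagnosis, carries prognostic information beyond clinicopathological staging:
trait derivation and QC, Cox proportional-hazards association scans,
discrimination metrics for clinical versus glyco-clinical risk models, glycan
variable selection, and a stage-stratified "rapid progressor" classification
comparison.

Because patient-level cohorts of this kind are not publicly deposited, the
package ships a synthetic cohort generator that emulates the study design --
compositional 24-peak profiles with plate-wise technical standards, clinical
marginals near the published cohort summary, and Weibull
proportional-hazards survival with the published stage hazard structure
planted as ground truth. Every downstream stage is tested against that known
truth.

## Glycomics: normalisation, traits, robustness

Raw peak areas are normalised by the total chromatogram area and expressed
in percent, so every analysable well sums to 100; this removes per-well
intensity and measures glycome composition per molecule of IgG. Derived
traits are ratios of summed peak percentages: each trait is
`scale * sum(numerator) / sum(denominator)` with `scale = 100` for
percentages (numerator a subset of the denominator) and `scale = 1` for pure
ratios such as `FBS1/FS1`. The neutral-glycome traits (`GPkn`, `G0n`, `G1n`,
`G2n`, `Fn`, `FBn`, ...) use the sialic-acid-free peak subset as denominator,
so `G0n + G1n + G2n = 100` holds identically for every sample.

The peak-to-structure mapping is deliberately not hard-coded: it lives in a
single packaged, overridable table (`inst/extdata/gp24_annotation.tsv`)
following the standard 24-peak convention, and all trait definitions are
generated from it (or read from a text config). The packaged panel comprises
the 24 measured percentages, 15 neutral percentages and 24 derived ratios
(63 traits); published panels count 77 traits over a slightly different
derived set, and the definition file is authoritative for this artifact.

Quality control uses the plate standards: each plate carries 3 biologically
identical wells, so their variance is purely experimental. For each trait,
robustness is `100 * Var(standards) / Var(cohort)` (unbiased variances,
standards pooled across plates after the same normalisation as samples).
Traits with robustness strictly below 20% are retained -- the comparison is
strict, so a trait at exactly 20.0 is excluded. For per-SD hazard ratios,
traits are rank-normalised with the Blom offset,
`qnorm((rank - 3/8)/(n + 1/4))`, average ranks for ties; the transform is
applied within each analysis subset so stratified scans stay per-SD of the
stratum.

## The synthetic cohort generator

The generator's defaults are the study conditions, not tuning knobs:

* **Cohort**: n = 1229; AJCC stage probabilities (249, 421, 413, 146)/1229;
  age ~ Normal(59, 10) truncated to [30, 90]; 43% female; 41% rectal tumours;
  BMI ~ Normal(26.6, 4.4) with 172/1229 missing completely at random; CRP
  log-normal (sdlog 1.4) calibrated so 130/1229 exceed 10 mg/l;
  operation-to-sampling time log-normal with median 5.4 months.
* **Glycome**: logistic-normal compositions centred on a mean profile
  calibrated so derived trait means sit near the published survivor column
  (G0n ~ 38, G1n ~ 44, G2n ~ 17.5, Fn ~ 79, FBn ~ 17). Logistic-normal
  rather than Dirichlet noise because plate shifts, well noise and biological
  effects then act additively on log-ratios -- the multiplicative error
  structure the robustness statistic assumes. Biological log-ratio SD is
  `1/sqrt(peak_concentration)` (default 0.25); plate shifts and well noise
  have SD `technical_sd` (default 0.05, giving robustness values well inside
  the 20% rule); a latent per-patient score with SD `glycan_axis_sd`
  (default 0.3) moves the galactosylation/sialylation axis (agalactosylated
  peaks up, digalactosylated and sialylated peaks down). With 0.3 the derived
  trait G0n correlates about 0.85 with the latent score, so a planted hazard
  effect of 0.3 per latent SD appears as a per-SD trait hazard ratio near
  1.29 -- the magnitude of the published trait table.
* **Survival**: Weibull baseline (shape 1.2, scale 29 years, chosen so
  stage-1 ten-year mortality is near the published 22%) with linear
  predictor = stage log-HRs (defaults log 1.35 / 2.65 / 14.32 for stages
  2--4, the published univariate values) + 0.02 per year of age + log 2.13
  for CRP > 10 mg/l + 0.3 per SD of the latent glycan score. Deaths are
  labelled CRC-caused by a stage-dependent Bernoulli draw (fractions from the
  published stage-specific death counts): cause is a label on observed
  deaths, not a competing hazard. Accrual is uniform over a 7-year window
  with an administrative censor date 14 years after study start, so censoring
  durations are `max(0, 14 - offset)` ~ Uniform(7, 14) years -- matching the
  published median follow-up of about 10 years for survivors. A zero censor
  window censors everyone at recruitment with zero events.
* **Plates**: 96 wells with 3 standards each. The published work does not
  report plate layout; 96 is the assay-standard assumption and is recorded
  in the config.

What the generator does *not* emulate: chromatogram traces, retention-time
calibration, peak integration error correlated across neighbouring peaks,
batch drift over calendar time, or clinical covariates correlated with stage
(age, CRP and stage are drawn independently). Passing tests therefore
demonstrate correctness of the statistical machinery under the planted
model, not robustness to those real-data features.

## Survival analysis

`fit_cox` fronts `survival::coxph` with Efron tie handling (registry
follow-up in years produces ties; the publication is silent, and Efron is
the accepted default), complete-case analysis per model with dropped-row
counts reported, and explicit errors for zero events, constant covariates
and monotone likelihoods (|log HR| > 20). Wald 95% intervals and p-values
are reported, matching the "HR (95% CI)" presentation convention. Three
adjustment sets mirror the study design: Model I crude, Model II age + sex +
stage, Model III additionally BMI, operation-to-sampling time, operation
type and CRP > 10 mg/l. Scans run on the whole cohort, excluding stage 4, or
within single stages (stage leaves the adjustment set there, and the
rank-normal transform is re-applied within the stratum).

The Benjamini--Hochberg family is the set of retained traits within one
outcome x model x subset scan. The published q/p ratios are not consistent
with m = 39 within one column (e.g. p = 2.6e-5 with q = 8e-4 implies a
larger correction universe that the authors do not state); this package
documents its family definition and applies standard BH to it. Traits whose
fit fails are reported with the failure reason and excluded from the family.

Diagnostics: proportional hazards via scaled Schoenfeld residuals against
event-time rank (`cox.zph`, transform "rank"); linearity screened by a
likelihood-ratio test of the continuous covariate against its
quartile-categorical version. Deviating PH for stage in whole-sample models
is expected (as noted in the source study); whole-sample models are still
fitted, with the diagnostic available.

For 5-year risks, `predict_risk` uses the Breslow baseline cumulative hazard
at covariates zero, `1 - exp(-H0(t) exp(lp))`; a horizon beyond follow-up
re-uses the last baseline step and says so.

## Discrimination

Harrell's C counts patient pairs whose ordering is determinable under right
censoring (the shorter time ends in an event, times strictly different),
with risk ties worth one half -- this makes `C(risk) + C(-risk) = 1` exact.
The cumulative/dynamic AUC at horizon t estimates
P(risk_i > risk_j | T_i <= t < T_j) with the Kaplan--Meier recursion: the
case distribution puts each failing subject's KM mass at their marker value,
the control distribution is the empirical marker distribution minus that
spent mass, normalised by S(t). Without censoring this reduces exactly to
the Mann--Whitney statistic on I(T <= t). The IDI is the difference in
discrimination slopes (mean predicted probability in events minus
non-events) between two models. Patients censored before the horizon have
unknowable 5-year status and are excluded from the slope computation (the
count is reported); the horizon defaults to 5 years and is a parameter,
since the published headline AUC does not state its horizon.

## Glycan selection

Bootstrap importance fits gradient-boosted Cox models of depth-1 trees
(stumps) on resamples of the cohort -- learning rate 0.01 and up to 2000
iterations by default, the stopping iteration optionally chosen on inner
folds; these are conservative defaults recorded in the configuration, since
the source names the method but no hyperparameters. Per-model relative
influence is normalised to sum to 100 before averaging so bootstraps are
comparable; ties in aggregate importance break lexicographically, making the
ranking reproducible and column-order invariant. Forward selection walks the
ranking once, adding a trait when the likelihood-ratio statistic against the
current model exceeds the chi-squared(1) critical value at alpha = 0.05
(the alpha and single-pass stopping rule are this package's documented
defaults, not inferred authors' choices), stopping after one failure by
default.

The penalised comparison fits L1-penalised Cox paths with clinical terms
unpenalised (penalty factor 0) and glycans penalised, the penalty chosen by
inner cross-validated partial-likelihood deviance; outer folds evaluate both
families on identical validation sets via the partial-likelihood deviance of
the validation linear predictor, giving a paired per-fold difference and
t-interval.

## Rapid progressors and the comparison protocol

A rapid progressor died of CRC with follow-up in the lower tertile of
CRC-death times within their stage; the cutoff uses linear-interpolation
(type 7) percentiles so printed cutoffs are reproducible against any
re-analysis. Stages with fewer than 3 CRC deaths are skipped with an
explicit reason (generalising the stage-1 skip). The 5-year classification
labels CRC death within 5 years as positive, event-free follow-up past 5
years or other-cause death as negative, and excludes (rather than imputes)
patients censored early -- the least-assumption option, with counts logged.

The cross-validation harness assigns stratified folds per run; filtering and
transforms are fitted on training folds only, and hyperparameters can be
chosen on inner folds of the training data. The merged AUC pools validation
predictions within a run and averages the per-run AUCs, keeping runs
independent for the paired comparison. The model zoo holds seven classes
(L1-logistic, nearest neighbours, nearest shrunken centroids, SVM with
linear/quadratic/cubic kernels, kernel-density naive Bayes, decision tree,
boosted stumps) behind one fit/predict contract; shrunken centroids and
kernel-density naive Bayes are native implementations, the rest bind to
glmnet, class, e1071, rpart and xgboost. Inner-fold tuning (lasso penalty,
neighbour count, centroid shrinkage, boosting iterations) is implemented and
available via `default_model_zoo(tuned = TRUE)`; the default zoo fixes these
at conservative values because, on the shipped benchmarks, tuning changes
neither the calibration nor the power of the with/without comparison while
costing about six times the runtime.

The stage-4-like benchmark (`simulate_progression_features`) draws n = 150
patients with three clinical covariates (one weakly informative), a latent
glycome axis, and five glycan features measuring that axis with noise SD
0.7 -- so each feature correlates about 0.8 with the axis, mirroring how the
real derived traits are correlated readouts of shared enzymatic activity.
Under the signal condition the axis raises the log odds of rapid progression
by 1.5 per SD; under the null it is unrelated to the labels. The paired Wilcoxon signed-rank test on with-minus-without AUC
differences is exact (convolution over sign assignments) for up to 25 untied
pairs, drops zero differences, and falls back to the tie-corrected normal
approximation when absolute differences tie; it is two-sided by default
(sidedness is a flag, as the source does not state it). The "Wd" variant
first collapses to one configuration per model class.

## Numerical choices and degenerate inputs

* Cox convergence: relative log-likelihood change below 1e-11, at most 50
  iterations; small-sample estimates agree with brute-force partial-
  likelihood maximisation to 1e-5.
* Zero-area wells are excluded with a warning; zero trait denominators give
  missing values for that sample only; missing trait values propagate and
  complete-case handling is decided per model.
* Robustness with zero cohort variance is undefined and the trait is not
  retained; rank-normalising a constant trait is an error surfaced as a scan
  note.
* All randomness flows from named seeds; identical seeds give bit-identical
  cohorts, fold assignments and reports. Numeric reports are written with
  17 significant digits so reruns byte-match.

## Problem sizes used by the test-suite

The shipped checks run the generator at the study scale (n = 1229) with 100
replicates for effect-recovery and FDR-control properties, 100 replicates of
the n = 150 stage-4-like benchmark with a 7-class zoo at 3 runs x 10-fold
cross-validation for the comparison protocol, and reduced bootstrap counts
(tens rather than 1000) for the selection checks; these sizes are the
package's chosen desk-scale defaults and the full-scale settings remain
available through the configuration.

## Anticonservatism of the paired comparison

The paired signed-rank comparison assumes the per-configuration AUC
differences are independent. They are not: all configurations are trained
and validated on the same dataset, so each replicate's realized spurious
alignment between glycans and labels moves every model's with-glycans AUC
in the same direction. On the shipped null benchmark the pairwise
correlation of configuration differences averages about 0.25 (linear-score
models such as the lasso and shrunken centroids correlate above 0.7), which
inflates the exact test's 5\% level to roughly 15\% -- and this proves
robust to inner-fold tuning, train-fold filtering, independent versus
correlated null glycans, per-configuration fold partitions, and 1--10
cross-validation runs. A significant p from this protocol on real data
should therefore be read as suggestive rather than calibrated evidence;
the positive finding it supports is qualitative (a consistent AUC gain
across disparate model classes), and the package reports the median gain
alongside the p-value for exactly that reason.

## Known limitations

* The annotation table, not the pipeline, carries the peak-to-structure
  truth; analyses of real chromatograms must verify it against their assay.
* Cause of death is a label, not a competing risk; no Fine--Gray models.
* No time-varying coefficients or frailty terms; the PH diagnostic warns but
  the models remain proportional-hazards.
* The generator's clinical covariates are mutually independent, which makes
  adjusted and crude scans nearly coincide on synthetic data -- unlike real
  cohorts, where staging confounds glycan associations.
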