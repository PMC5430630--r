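# homarg

Observational and Mendelian-randomization analysis of serum
L-homoarginine (hArg) and cardiometabolic health, packaged as a tested,
tidyverse-native R pipeline.

Serum hArg is a non-proteinogenic amino acid whose low levels have been
linked to cardiovascular mortality in older and diseased populations, while
in young adults it tracks *adverse* metabolic features. Disentangling
biomarker from cause requires (a) careful observational modelling in cohort
data — cross-sectional metabolome-wide scans, determinants of hArg, and
incident-outcome models over follow-up — and (b) two-sample Mendelian
randomization (MR), which uses hArg-associated genetic variants (*GATM*
rs1153858, *CPS1* rs1047891, *AGXT2* rs37369) as instruments against GWAS
summary statistics for metabolic and disease outcomes. This package
implements both arms for epidemiologists and genetic-epidemiology
practitioners, together with calibrated synthetic-data generators so that
every stage runs and is testable without access to individual-level cohort
data or consortium files.

## What it computes

**Phenotyping** (`classify_records()`, `incident_risk_set()`): harmonized
metabolic-syndrome components (waist ≥ 102/88 cm by sex, triglycerides
> 1.7 mmol/L, HDL < 1.0/1.3 mmol/L, BP ≥ 130/85 mmHg or treatment, fasting
glucose ≥ 5.6 mmol/L), obesity (BMI ≥ 30), sex-specific > 90th-percentile
insulin, type 2 diabetes (glucose ≥ 7.0, HbA1c ≥ 6.5%, medication, or
diagnosis), coronary calcification (Agatston ≥ 1) and age/sex-percentile
carotid flags; incident sets exclude prevalent cases.

**Cross-sectional scan** (`prepare_metabolites()`,
`effective_test_threshold()`, `metabolome_scan()`): zeros → half the minimum
positive value, log transform, SD scaling (per sex for stratified scans);
the multiple-testing threshold is α/k where k is the number of principal
components explaining ≥ 95% of the metabolite variance; sex differences via
Z = (β_m − β_f)/√(SE_m² + SE_f²); hArg × BMI interaction terms;
bidirectional stepwise-AIC modelling of hArg determinants
(`stepwise_determinants()`).

**Incident models** (`fit_incident_model()`, `run_model_grid()`): logistic
regression of incident outcomes on SD-scaled ln hArg, unadjusted (Model 1),
plus baseline cardiometabolic risk factors (Model 2), plus SHBG and oral
contraceptive use in women (Model 3), reported as OR with Wald 95% CI.

**Two-sample MR** (`harmonize()`, `wald_ratio()`, `ivw_combine()`,
`cochran_q()`, `mr_grid()`): instrument strength F = (β_X/SE_X)²; allele
harmonization with palindromic-variant handling; per-SNP Wald ratios
θ_j = β_Yj/β_Xj with first-order SE = SE_Yj/|β_Xj|; the combined estimate is
the weighted regression of β_Y on β_X through the origin with weights
1/SE_Y²,

    θ̂ = Σ_j (β_Xj β_Yj / SE_Yj²) / Σ_j (β_Xj² / SE_Yj²),
    SE_fixed = 1 / sqrt(Σ_j β_Xj² / SE_Yj²),

with Cochran's Q = Σ_j w_j (θ_j − θ̂)², w_j = β_Xj²/SE_Yj², referred to
χ²_{J−1}, and a multiplicative random-effects SE
φ·SE_fixed, φ = max(1, √(Q/(J−1))) — the same point estimate as fixed
effects, never a narrower interval under heterogeneity.

**Synthetic data** (`generate_cohort()`, `generate_two_sample_summary()`):
a cohort calibrated to published baseline marginals (mean hArg
1.85 (SD 0.65) µmol/L, 54.6% women, lead variant explaining 5.3% of
ln-hArg variance, per-allele effect ≈ 0.25 µmol/L) and a two-sample
summary-statistics simulator with configurable causal effect, pleiotropy
and heterogeneity.

## Worked example

```r
library(homarg)

sim <- generate_two_sample_summary(summary_sim_params(true_effect = 0.1, seed = 42))
f_statistic(sim$exposure$beta, sim$exposure$se)
#>   f_statistic weak
#> 1        370. FALSE
#> 2        134. FALSE
#> 3        131. FALSE

h  <- harmonize(sim$exposure, sim$outcome)
iv <- ivw_combine(h)
iv
#> IVW causal estimate: 0.1084 (95% CI 0.0700 to 0.1467) per 1-unit exposure, p = 3.06e-08
#>   J = 3 instruments; Q = 0.244 on 2 df (p = 0.885); dispersion phi = 1.000
```

All three instruments are strong (F between ~130 and ~370, well above the
weak-instrument bound of 10). The simulated causal effect of 0.1 outcome
units per 1 µmol/L hArg is recovered as 0.108 with a tight interval, and
Cochran's Q (p = 0.885) shows no more heterogeneity between the per-variant
estimates than chance would produce. `tidy(iv)` and `glance(iv)` return the
same quantities as one-row tibbles; `autoplot()` draws forest plots for
grids of outcomes.

The full synthetic pipeline (cohort → phenotyping → scan → incident grid →
MR) runs with:

```r
run_pipeline(pipeline_config(out_dir = "demo", seed = 1))
```

or from a shell via the wrapper `inst/cli/homarg.R`
(`Rscript inst/cli/homarg.R all --seed 1 --out demo`).

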