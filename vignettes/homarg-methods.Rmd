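---
title: "Methods: homoarginine, cardiometabolic outcomes and two-sample MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoarginine, cardiometabolic outcomes and two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(homarg)
```

# Scope and design

`homarg` implements a complete analysis chain for studying serum
L-homoarginine (hArg, µmol/L) against cardiometabolic outcomes: rule-based
phenotyping of prevalent and incident conditions, a sex-stratified
metabolome-wide association scan with an effective-number-of-tests
correction, bidirectional stepwise-AIC modelling of hArg determinants,
incident-outcome logistic models, and a two-sample summary-level Mendelian
randomization (MR) engine. Because the individual-level cohort and the
consortium summary files behind such analyses are access-restricted, the
package ships calibrated synthetic-data generators; every stage is
exercised, and tested, on data the package itself can produce.

The package is tidyverse-native: every user-facing function takes a data
frame first and returns a tibble, fitted objects have `tidy()`/`glance()`
methods, and result tables have `autoplot()` displays. This shape was
chosen because all inputs and outputs are naturally tabular (participant
rows, per-SNP summary rows, long-format result grids).

# Phenotyping rules

`classify_records()` is a deterministic rule engine. Thresholds follow the
harmonized metabolic-syndrome criteria and related clinical definitions:
waist circumference ≥ 102 cm (men) / ≥ 88 cm (women); triglycerides
strictly > 1.7 mmol/L; HDL < 1.0 / < 1.3 mmol/L; blood pressure ≥ 130
systolic **or** ≥ 85 mmHg diastolic or antihypertensive treatment; fasting
glucose ≥ 5.6 mmol/L (or diagnosed type 2 diabetes) for hyperglycaemia;
BMI ≥ 30 kg/m² for obesity; fasting glucose ≥ 7.0 mmol/L, HbA1c ≥ 6.5%,
glucose-lowering medication without type 1 diabetes, or physician diagnosis
for type 2 diabetes; Agatston score ≥ 1 for coronary calcification. High
insulin uses follow-up fasting insulin strictly above the sex-specific
90th percentile; high-risk carotid intima-media thickness (IMT) and low
distensibility use age- and sex-specific 90th/10th percentiles.

Decisions where the definitions leave room:

* **Missingness.** A flag whose required inputs are missing is `NA`, never
  `FALSE`: absence of evidence is not evidence of absence, and silently
  treating unmeasured participants as unaffected would bias incidence down.
* **Treatment-only blood pressure.** Antihypertensive treatment alone sets
  the BP flag even when measured pressures are missing; the rule's "or
  treatment" arm does not require a measurement. A message reports how many
  records were decided this way, so the choice is auditable.
* **Quantile definition.** Percentile cuts use linear interpolation of the
  empirical CDF (type 7, the R default); the type is recorded in the
  reference table so an alternative convention can be swapped in.
* **Age bands.** "Age- and sex-specific" percentiles for IMT and
  distensibility default to 3-year age bins crossed with sex — narrow
  enough to track the age gradient in a young-adult cohort, wide enough to
  keep ≥ tens of observations per stratum; the bin width is an argument.
* **BMI boundary.** Obesity is BMI ≥ 30 (inclusive), matching the
  operational definition used with the other inclusive cut-offs.

`incident_risk_set()` implements the standard incident-outcome bookkeeping:
participants with the condition at baseline are excluded; among the rest,
only those with an observed follow-up flag are at risk; incident cases are
at-risk participants whose follow-up flag is set.

# Metabolite preparation and the effective number of tests

`prepare_metabolites()` replaces zero concentrations by half the column's
minimum positive value (a detection-limit surrogate that keeps the log
transform defined without discarding censored values), takes natural logs,
and centres/scales each column to SD 1 — within sex for sex-stratified
analyses, since metabolite distributions differ systematically by sex.
Entirely-zero columns are an error (no detection limit can be estimated),
as are zero-variance columns (they cannot be standardized).

Because NMR metabolite panels are strongly correlated (lipoprotein
subclasses in particular are near-duplicates), a Bonferroni correction over
the raw column count would be far too severe. `effective_test_threshold()`
computes the eigenvalues of the metabolite correlation matrix and takes
`k`, the smallest number of principal components whose cumulative explained
variance reaches the target (default 0.95); the per-test threshold is
α/k. On a panel whose correlation structure is dominated by ~25 blocks
this yields a threshold of 0.05/25 = 0.002.

One numerical subtlety: when two or more eigenvalues are numerically equal
(relative tolerance 1e-8), the corresponding principal components span a
subspace in which individual components are not identifiable, so the count
never splits a tied multiplet — if the variance target is reached inside a
run of equal eigenvalues, the whole run is included. On degenerate panels
(blocks of duplicated columns, where the spectrum is a set of repeated
values) this makes `k` equal the number of distinct blocks, which is the
scientifically meaningful count of independent signals; on real data, where
sample eigenvalues are almost surely distinct, the refinement never fires.

# The association scan, sex differences and interactions

`metabolome_scan()` fits, per metabolite and sex stratum, a linear model
with the prepared metabolite as outcome and SD-scaled ln hArg as exposure,
adjusted by default for age, BMI, daily smoking, ln SHBG and (in women)
oral-contraceptive use. Effects are therefore in SD units of metabolite per
1-SD ln hArg. P-values use the t distribution with residual degrees of
freedom — at stratum sizes around 10³ the normal approximation is
unnecessary. hArg is log-transformed and SD-scaled within the same strata
as the metabolites (per-sex when the scan is stratified), keeping exposure
and outcome scales aligned; pooled scaling is available by preparing the
matrix unstratified.

Sex differences are tested with the Z-statistic
Z = (β_men − β_women)/√(SE²_men + SE²_women), two-sided against the
standard normal; `bmi_interaction()` adds an hArg × BMI product term to the
stratified model and reports its coefficient. Both are judged against the
effective-tests threshold, not 0.05.

`stepwise_determinants()` models ln hArg on candidate risk factors by
bidirectional stepwise selection under AIC, starting from the full model
(the default behaviour of the classical stepwise implementation it wraps);
at every step all single additions and deletions are evaluated and the best
move applied until no move lowers AIC, so the returned model is a local
optimum of the add/drop neighbourhood — the test suite verifies this
against an exhaustive neighbour enumeration. AIC is the Gaussian
log-likelihood form; only differences matter, and ties resolve toward the
smaller model. Perfectly collinear candidates are removed (with a warning)
before the search because they make the move comparison ill-defined.

# Incident-outcome models

`fit_incident_model()` is maximum-likelihood logistic regression of an
incident flag on SD-scaled ln baseline hArg within one sex stratum, at
three nested adjustment tiers: unadjusted; plus the baseline
cardiometabolic risk factors (age, LDL, HDL, ln triglycerides, systolic and
diastolic BP, ln CRP, glucose, ln insulin, BMI, waist, daily smoking,
family history of coronary disease — sex is excluded because fits are
sex-stratified); plus ln SHBG and, in women, oral-contraceptive use.
Right-skewed covariates (CRP, triglycerides, insulin, SHBG) enter on the
log scale. BMI and waist are both retained despite their collinearity —
neither defines the other's outcome here — with a warning when their
correlation exceeds 0.9. Family history is included in the adjusted tiers
as one of the baseline risk factors.

Odds ratios are per 1-SD ln hArg with Wald 95% intervals (symmetric on the
log scale). Zero events raise an error rather than returning a degenerate
fit; a runaway coefficient or standard error (|β| or SE > 10) flags
probable quasi-complete separation. `run_model_grid()` iterates the fits
over outcome × tier × sex and annotates failed cells instead of aborting,
so one empty risk set cannot destroy a forest table.

# Two-sample Mendelian randomization

The MR engine assumes the three standard instrumental-variable conditions:
the variants are associated with hArg (checked via F = (β_X/SE_X)², flagged
weak below 10), affect outcomes only through hArg (probed, not guaranteed,
by Cochran's Q), and are independent of confounders.

`harmonize()` aligns outcome rows to the exposure's effect allele: matching
alleles are kept, swapped alleles flip the outcome beta, strand-complement
labels are resolved by complementing, and palindromic (A/T, G/C) variants —
where strand cannot be inferred from labels — are resolved by allele
frequency only when both sides report one on the same side of 0.5 and
neither is within 0.08 of 0.5; otherwise they are dropped with the reason
recorded. Guessing strand for ambiguous palindromes risks silently flipping
an effect, which is worse than losing an instrument.

`ivw_combine()` is authored directly from the estimator's definition:
weighted regression of β_Y on β_X through the origin with first-order
weights 1/SE_Y². The fixed-effects standard error is 1/√(Σβ_X²/SE_Y²);
the multiplicative random-effects model multiplies it by
φ = max(1, √(Q/(J−1))). The floor at 1 means under-dispersion never makes
the random-effects interval *narrower* than fixed effects — the model's
purpose is to avoid overprecision under heterogeneity, not to reward
homogeneity. The causal p-value uses the normal distribution (summary-level
asymptotics) with the random-effects SE; with the φ floor this makes the
test slightly conservative under exact homogeneity, a deliberate trade.
Cochran's Q uses weights β_X²/SE_Y² and the χ²(J−1) reference; it is
undefined (error) below two instruments. Estimates are per 1 µmol/L hArg;
if exposure betas arrive per SD, `scale_factor` (e.g. 0.65 µmol/L, the
population SD of hArg) converts them before combination rather than
assuming a scale.

The algebraically identical "weighted mean of Wald ratios" form is *not*
the implementation; it serves as an independent identity in the tests,
alongside a generic weighted-least-squares oracle that must agree with the
closed form to 1e-10.

# The synthetic-data generators

`generate_cohort()` emulates a young-adult cohort of 2,106 participants
(54.6% women) with per-sex baseline marginals in clinical units (e.g. hArg
1.85 (0.65) µmol/L overall, ln hArg 0.56 (0.34); BMI 25.6/24.4 kg/m²;
right-skewed traits log-normal). ln hArg is built additively: intercept,
a male–female difference of 0.09 log units, per-allele contributions of
three Hardy-Weinberg variants (effect-allele frequency 0.3 each — a
mid-range value, since the source cohort does not publish them), and
Gaussian noise sized so the total SD matches 0.34. The lead-variant
per-allele effect is solved analytically so its expected variance share
equals `variance_explained_lead` (default 0.053); when that is unset the
effect defaults to a 0.25 µmol/L raw-scale increment per allele
(ln(1 + 0.25/1.85) on the log scale), about a 14% increase on the mean.
The secondary variants contribute ~2% of variance each, sized so that
simulated GWAS F-statistics land in the 120–370 range at the exposure GWAS
size of 5,143.

Metabolites come in 25 equicorrelated blocks of 9 (within-block correlation
0.99, so the block structure — like near-duplicate lipoprotein subclasses —
dominates the correlation spectrum and the effective-tests procedure
returns a divisor near 25). Block 1 carries a planted association of −0.3
SD per SD ln hArg (a strong negative, glycine-like signal) and block 2
+0.2; the rest are null. Concentrations are log-normal, hence
non-negative, with 0.5% of entries censored to zero to exercise the
detection-limit replacement. Incident outcome flags are drawn from
logistic models on sex-scaled ln hArg with intercepts giving 4–15%
incidence and odds ratios of 1.2–1.55 per SD; follow-up traits carry over
from baseline through an AR(1) term (coefficient 0.6) with modest mean
drift, and attendance at each wave is Bernoulli(0.85).

`generate_two_sample_summary()` draws per-SNP exposure and outcome summary
rows with independent noise (no sample overlap):
β̂_X ~ N(β_X, SE_X²), β̂_Y ~ N(θβ_X + α + η, SE_Y²), η ~ N(0, τ²), with
SE = sd/√(2p(1−p)n). The defaults use the exposure GWAS size 5,143 and an
outcome GWAS of 50,000.

**What the generators do not emulate** — and hence what passing tests do
not establish about real data: linkage disequilibrium between variants
(the three instruments are treated as independent, as their genomic
locations justify), assay measurement error and batch effects, non-random
missingness and attrition correlated with health, population stratification,
and real metabolite networks beyond block equicorrelation. Calibration
checks on simulated data validate the *estimators*, not the epidemiology.

# Problem sizes and numerical tolerances

The test suite validates the estimators at sizes chosen to make Monte-Carlo
error small relative to the tolerance while keeping the default run fast:
variance-share calibration at n = 50,000 (tolerance band 0.045–0.061 around
0.053); null calibration of the causal and heterogeneity p-values over
2,000 replicates (empirical 5% rates within ±0.015); effect recovery for
θ ∈ {0.1, 0.5} over 1,000 replicates at GWAS sizes 50,000/200,000, where
regression-dilution bias from noisy instrument betas is an order of
magnitude below the Monte-Carlo resolution; heterogeneity power under a
direct (pleiotropic) CPS1-variant effect of 0.25 at an outcome GWAS of
100,000, sized by a noncentral-χ² power calculation to exceed 0.8;
logistic effect recovery over 500 replicates at n = 5,000. Closed-form
identities (Wald ratio, IVW vs weighted least squares, 2×2 odds ratio) are
asserted at 1e-6–1e-10.

# Known limitations

* The stepwise procedure inherits the well-known instability of stepwise
  selection; it reports a locally AIC-optimal model, not an inference-valid
  one, and post-selection p-values should be read descriptively.
* Wald intervals for the incident models are first-order; profile intervals
  are not currently wired in, and separation is flagged rather than
  penalized (no Firth correction).
* The MR engine implements the inverse-variance weighted family only;
  pleiotropy-robust estimators (MR-Egger, weighted median, mode-based) are
  out of scope, as is LD-aware multi-variant modelling. First-order weights
  ignore the uncertainty in β_X; with F ≥ 120 the second-order correction
  is negligible, but for weak instruments it would not be.
* Time-to-event structure is deliberately ignored: incidence is binary over
  a fixed horizon, so differential follow-up time is not modelled.
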