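#' Parameters for the synthetic cohort generator
#'
#' Builds the parameter object consumed by [generate_cohort()]. Defaults
#' emulate a young-adult Finnish cohort: per-sex baseline trait means and SDs,
#' 54.6% women, serum homoarginine (hArg) with mean 1.85 and SD 0.65 µmol/L,
#' and three independent hArg-associated variants (GATM rs1153858, CPS1
#' rs1047891, AGXT2 rs37369) of which the lead GATM variant explains 5.3% of
#' the variance in log hArg.
#'
#' Log hArg is constructed as an additive model
#' `ln(hArg) = mu + b_sex * male + sum_j b_j * (dosage_j - 2 p_j) + eps`,
#' with the lead per-allele effect `b_1` solved so that its expected variance
#' share `b_1^2 * 2 p (1 - p) / sd_ln^2` equals `variance_explained_lead`.
#' When `variance_explained_lead` is `NULL` the lead effect defaults to a
#' per-allele increment of 0.25 µmol/L on the raw scale
#' (`b_1 = ln(1 + 0.25 / 1.85)`).
#'
#' Metabolites are generated in `n_blocks` equicorrelated blocks of
#' `block_size` measures (within-block correlation `block_rho`); block `b`
#' carries a planted association `metabolite_betas[b]` with SD-scaled log hArg,
#' in SD units per SD. Concentrations are log-normal and therefore
#' non-negative; a small fraction `zero_rate` of entries is censored to zero
#' to emulate values below the detection limit.
#'
#' Incident outcome status at the 6/7/10-year horizons is drawn from logistic
#' models `logit P(flag) = intercept + log_or_per_sd * z` where `z` is log
#' hArg SD-scaled within sex; `outcome_log_odds` configures one row per
#' outcome. Follow-up trait values carry over from baseline through an AR(1)
#' term with coefficient `ar_rho`, and attendance at each follow-up wave is
#' Bernoulli(`attendance`).
#'
#' @param n_participants Number of participants (>= 2).
#' @param female_fraction Proportion of women in `[0, 1]`.
#' @param baseline Tibble of per-sex trait marginals with columns
#'   `trait, mean_m, sd_m, mean_f, sd_f`; see `default_baseline_marginals()`.
#' @param snps Tibble with columns `rsid, gene, effect_allele, other_allele,
#'   eaf, beta_ln` (per-allele effect on log hArg; the lead row's `beta_ln`
#'   is overridden when `variance_explained_lead` is set).
#' @param variance_explained_lead Variance share of log hArg attributed to
#'   the lead variant, or `NULL` to use the 0.25 µmol/L per-allele default.
#' @param ln_harg_mean,ln_harg_sd Targeted marginal mean and SD of log hArg.
#' @param sex_effect_ln Male-minus-female difference in mean log hArg.
#' @param n_blocks,block_size,block_rho,metabolite_betas,metabolite_log_sd,zero_rate
#'   Metabolite block structure (see Details).
#' @param outcome_log_odds Tibble with columns `outcome, horizon, intercept,
#'   log_or_per_sd` for the incident-outcome logistic generator.
#' @param attendance Follow-up attendance probability per wave.
#' @param ar_rho AR(1) carry-over of trait z-scores from baseline to follow-up.
#' @param smoking_prob Named numeric, daily-smoking prevalence for
#'   `male`/`female`.
#' @param family_history_prob Prevalence of family history of CAD.
#' @param oc_prob Oral-contraceptive use prevalence among women.
#' @param seed Integer seed; the generator is a pure function of parameters
#'   and seed.
#'
#' @return A list of class `"cohort_params"`.
#' @export
cohort_params <- function(n_participants = 2106L,
                          female_fraction = 0.546,
                          baseline = default_baseline_marginals(),
                          snps = default_instrument_snps(),
                          variance_explained_lead = 0.053,
                          ln_harg_mean = 0.56,
                          ln_harg_sd = 0.34,
                          sex_effect_ln = 0.09,
                          n_blocks = 25L,
                          block_size = 9L,
                          block_rho = 0.99,
                          metabolite_betas = default_metabolite_betas(n_blocks),
                          metabolite_log_sd = 0.5,
                          zero_rate = 0.005,
                          outcome_log_odds = default_outcome_log_odds(),
                          attendance = 0.85,
                          ar_rho = 0.6,
                          smoking_prob = c(male = 0.301, female = 0.202),
                          family_history_prob = 0.133,
                          oc_prob = 0.3,
                          seed = 1L) {
  assert_that(is.numeric(n_participants) && n_participants >= 2,
              "n_participants must be at least 2")
  assert_that(is_proportion(female_fraction), "female_fraction must be in [0, 1]")
  assert_that(is_proportion(c(attendance, zero_rate, oc_prob, family_history_prob,
                              unname(smoking_prob))),
              "probabilities must be in [0, 1]")
  assert_that(all(c("trait", "mean_m", "sd_m", "mean_f", "sd_f") %in% names(baseline)),
              "baseline must have columns trait, mean_m, sd_m, mean_f, sd_f")
  assert_that(all(baseline$sd_m > 0) && all(baseline$sd_f > 0),
              "baseline SDs must be positive")
  assert_that(all(snps$eaf > 0 & snps$eaf < 1),
              "effect-allele frequencies must lie strictly inside (0, 1)")
  if (!is.null(variance_explained_lead)) {
    assert_that(is_proportion(variance_explained_lead) && variance_explained_lead > 0,
                "variance_explained_lead must be in (0, 1]")
  }
  assert_that(length(metabolite_betas) == n_blocks,
              "metabolite_betas must have one entry per block")
  assert_that(all(metabolite_betas^2 <= block_rho),
              "metabolite_betas^2 must not exceed block_rho")

  structure(
    list(
      n_participants = as.integer(n_participants),
      female_fraction = female_fraction,
      baseline = baseline,
      snps = snps,
      variance_explained_lead = variance_explained_lead,
      ln_harg_mean = ln_harg_mean,
      ln_harg_sd = ln_harg_sd,
      sex_effect_ln = sex_effect_ln,
      n_blocks = as.integer(n_blocks),
      block_size = as.integer(block_size),
      block_rho = block_rho,
      metabolite_betas = metabolite_betas,
      metabolite_log_sd = metabolite_log_sd,
      zero_rate = zero_rate,
      outcome_log_odds = outcome_log_odds,
      attendance = attendance,
      ar_rho = ar_rho,
      smoking_prob = smoking_prob,
      family_history_prob = family_history_prob,
      oc_prob = oc_prob,
      seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

#' Default per-sex baseline trait marginals
#'
#' Mean (SD) of the baseline cardiometabolic risk factors by sex, in the
#' usual clinical units: lipids mmol/L, blood pressure mmHg, BMI kg/m^2,
#' waist cm, insulin IU/L, glucose mmol/L, CRP mg/L, HbA1c %, SHBG nmol/L,
#' carotid intima-media thickness (IMT) mm, carotid distensibility %/10 mmHg.
#'
#' @return A tibble with columns `trait, mean_m, sd_m, mean_f, sd_f, dist`
#'   where `dist` is `"normal"` or `"lognormal"` (right-skewed traits).
#' @export
default_baseline_marginals <- function() {
  tibble::tribble(
    ~trait,     ~mean_m, ~sd_m, ~mean_f, ~sd_f, ~dist,
    "age",        31.6,    5.0,   31.7,    5.0, "normal",
    "ldl",         3.42,   0.90,   3.14,   0.77, "normal",
    "hdl",         1.17,   0.27,   1.39,   0.30, "normal",
    "tg",          1.41,   0.70,   1.13,   0.55, "lognormal",
    "sbp",       121,     12,    113,     12,   "normal",
    "dbp",        73,     11,     69,     10,   "normal",
    "crp",         1.5,    3.4,    2.1,    4.4, "lognormal",
    "glucose",     5.2,    0.93,   4.9,    0.75, "normal",
    "insulin",     7.6,    5.8,    7.8,    5.7, "lognormal",
    "bmi",        25.6,    4.1,   24.4,    4.5, "normal",
    "waist",      90,     11,     79,     11,   "normal",
    "hba1c",       5.3,    0.35,   5.2,    0.35, "normal",
    "shbg",       35,     14,     60,     30,   "lognormal",
    "imt",         0.58,   0.09,   0.56,   0.08, "normal",
    "dist_car",    2.1,    0.65,   2.3,    0.70, "normal"
  )
}

#' Default instrument variants
#'
#' The three independent hArg-associated variants used as genetic
#' instruments. Effect-allele frequencies default to 0.3 (not reported in the
#' source cohort); per-allele effects on log hArg are sized so the secondary
#' variants explain roughly 2–3% of log-hArg variance each.
#'
#' @return A tibble with columns `rsid, gene, effect_allele, other_allele,
#'   eaf, beta_ln`.
#' @export
default_instrument_snps <- function() {
  tibble::tibble(
    rsid = c("rs1153858", "rs1047891", "rs37369"),
    gene = c("GATM", "CPS1", "AGXT2"),
    effect_allele = c("A", "A", "T"),
    other_allele = c("G", "C", "C"),
    eaf = c(0.3, 0.3, 0.3),
    beta_ln = c(0.121, 0.08, 0.07)
  )
}

#' @rdname cohort_params
#' @export
default_metabolite_betas <- function(n_blocks = 25L) {
  betas <- rep(0, n_blocks)
  # one strongly negative block (glycine-like) and one moderate positive block
  betas[1] <- -0.3
  betas[2] <- 0.2
  betas
}

#' Default incident-outcome logistic parameters
#'
#' One row per incident outcome: the follow-up horizon in years, the logistic
#' intercept (controls marginal incidence) and the log odds ratio per 1-SD
#' increment in log hArg.
#'
#' @return A tibble with columns `outcome, horizon, intercept, log_or_per_sd`.
#' @export
default_outcome_log_odds <- function() {
  tibble::tribble(
    ~outcome,             ~horizon, ~intercept,      ~log_or_per_sd,
    "obesity",                  10, qlogis(0.10),    log(1.30),
    "abdominal_obesity",        10, qlogis(0.15),    log(1.30),
    "hyperglycaemia",           10, qlogis(0.15),    log(1.31),
    "high_insulin",             10, qlogis(0.10),    log(1.30),
    "t2dm",                     10, qlogis(0.04),    log(1.55),
    "cac_present",               7, qlogis(0.10),    log(1.20),
    "high_risk_imt",             6, qlogis(0.10),    log(1.30),
    "low_distensibility",        6, qlogis(0.10),    log(1.20)
  )
}

#' Generate a synthetic cohort table
#'
#' Draws one row per participant: sex, age, genotype dosages at the three
#' instrument variants (Hardy-Weinberg), serum hArg built from the additive
#' genetic model described in [cohort_params()], baseline risk factors
#' matching the requested per-sex marginals, NMR-style metabolite
#' concentrations in correlated blocks, medication/diagnosis flags, and
#' follow-up columns: attendance indicators, follow-up trait values (AR(1)
#' carry-over) and incident-outcome flags drawn from the configured logistic
#' models (set to `NA` for non-attendees).
#'
#' @param params A [cohort_params()] object.
#' @return A tibble with one row per participant and attribute `"params"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_participants = 200, seed = 7))
#' dplyr::count(cohort, sex)
generate_cohort <- function(params = cohort_params()) {
  assert_that(inherits(params, "cohort_params"),
              "params must be created by cohort_params()")
  set.seed(params$seed)
  n <- params$n_participants

  sex <- ifelse(runif(n) < params$female_fraction, "female", "male")
  male <- as.numeric(sex == "male")

  # genotypes under Hardy-Weinberg
  snps <- params$snps
  dosages <- vapply(snps$eaf, function(p) rbinom(n, 2L, p), numeric(n))
  colnames(dosages) <- paste0("dosage_", snps$rsid)

  # per-allele effects on log hArg; lead effect solved from the variance
  # share, or defaulting to a 0.25 umol/L raw-scale per-allele increment
  beta_ln <- snps$beta_ln
  if (!is.null(params$variance_explained_lead)) {
    p1 <- snps$eaf[1]
    beta_ln[1] <- sqrt(params$variance_explained_lead * params$ln_harg_sd^2 /
                         (2 * p1 * (1 - p1)))
  } else {
    beta_ln[1] <- log(1 + 0.25 / 1.85)
  }
  genetic <- as.numeric(dosages %*% beta_ln) -
    sum(beta_ln * 2 * snps$eaf)

  var_gen <- sum(beta_ln^2 * 2 * snps$eaf * (1 - snps$eaf))
  pf <- params$female_fraction
  var_sex <- params$sex_effect_ln^2 * pf * (1 - pf)
  resid_sd <- sqrt(max(params$ln_harg_sd^2 - var_gen - var_sex, 1e-8))
  mu0 <- params$ln_harg_mean - params$sex_effect_ln * (1 - pf)

  ln_harg <- mu0 + params$sex_effect_ln * male + genetic + rnorm(n, 0, resid_sd)
  harg <- exp(ln_harg)

  # baseline traits, per-sex marginals; right-skewed traits are log-normal
  traits <- purrr::pmap(params$baseline, function(trait, mean_m, sd_m, mean_f, sd_f, dist) {
    m <- ifelse(male == 1, mean_m, mean_f)
    s <- ifelse(male == 1, sd_m, sd_f)
    if (dist == "lognormal") {
      sigma2 <- log(1 + (s / m)^2)
      exp(rnorm(n, log(m) - sigma2 / 2, sqrt(sigma2)))
    } else {
      rnorm(n, m, s)
    }
  })
  names(traits) <- params$baseline$trait
  traits <- tibble::as_tibble(traits)
  names(traits)[names(traits) == "dist_car"] <- "dist"

  smoking <- rbinom(n, 1L, unname(params$smoking_prob[ifelse(male == 1, "male", "female")]))
  family_history <- rbinom(n, 1L, params$family_history_prob)
  oc_use <- ifelse(sex == "female", rbinom(n, 1L, params$oc_prob), 0L)
  bp_treatment <- rbinom(n, 1L, 0.02)
  glucose_med <- rbinom(n, 1L, 0.005)
  t1dm_diag <- rbinom(n, 1L, 0.003)
  t2dm_diag <- rbinom(n, 1L, 0.005)

  # metabolite blocks: z = beta*h + sqrt(rho - beta^2)*f_block + sqrt(1 - rho)*e
  z_harg <- scale_ln_by(harg, sex)
  mets <- vector("list", params$n_blocks * params$block_size)
  met_names <- character(length(mets))
  k <- 0L
  for (b in seq_len(params$n_blocks)) {
    beta_b <- params$metabolite_betas[b]
    f_b <- rnorm(n)
    for (j in seq_len(params$block_size)) {
      k <- k + 1L
      z <- beta_b * z_harg +
        sqrt(params$block_rho - beta_b^2) * f_b +
        sqrt(1 - params$block_rho) * rnorm(n)
      conc <- exp(params$metabolite_log_sd * z)
      if (params$zero_rate > 0) {
        conc[runif(n) < params$zero_rate] <- 0
      }
      mets[[k]] <- conc
      met_names[k] <- sprintf("met_%02d_%d", b, j)
    }
  }
  names(mets) <- met_names
  mets <- tibble::as_tibble(mets)

  # follow-up attendance and AR(1) carry-over of trait z-scores
  attended_6y <- rbinom(n, 1L, params$attendance)
  attended_7y <- rbinom(n, 1L, params$attendance)
  attended_10y <- rbinom(n, 1L, params$attendance)

  fu_trait <- function(x, drift, wave_attended) {
    m <- mean(x)
    s <- sd(x)
    z <- (x - m) / s
    out <- m + drift + s * (params$ar_rho * z + sqrt(1 - params$ar_rho^2) * rnorm(n))
    out[wave_attended == 0] <- NA_real_
    out
  }
  drift <- c(bmi = 1.5, waist = 4, glucose = 0.2, insulin = 0.8, tg = 0.1,
             hdl = 0, sbp = 2, dbp = 2, hba1c = 0.1)
  fu10 <- purrr::imap(drift, function(d, tr) fu_trait(traits[[tr]], d, attended_10y))
  names(fu10) <- paste0(names(drift), "_10y")
  fu10 <- tibble::as_tibble(fu10)
  fu10 <- dplyr::mutate(fu10,
                        insulin_10y = pmax(.data$insulin_10y, 0.5),
                        tg_10y = pmax(.data$tg_10y, 0.1))
  imt_6y <- fu_trait(traits$imt, 0.03, attended_6y)
  dist_6y <- fu_trait(traits$dist, -0.15, attended_6y)

  # incident outcome flags from the logistic models (NA off-wave)
  flags <- purrr::pmap(params$outcome_log_odds,
                       function(outcome, horizon, intercept, log_or_per_sd) {
    pr <- plogis(intercept + log_or_per_sd * z_harg)
    flag <- rbinom(n, 1L, pr)
    wave <- switch(as.character(horizon),
                   "6" = attended_6y, "7" = attended_7y, attended_10y)
    flag[wave == 0] <- NA_integer_
    flag
  })
  names(flags) <- paste0("fu_", params$outcome_log_odds$outcome)
  flags <- tibble::as_tibble(flags)

  # coronary calcium measured once, 7 years after baseline
  cac <- flags$fu_cac_present
  agatston_7y <- ifelse(is.na(cac), NA_real_,
                        ifelse(cac == 1, rpois(n, 30) + 1, 0))

  out <- dplyr::bind_cols(
    tibble::tibble(id = seq_len(n), sex = sex, harg = harg),
    tibble::as_tibble(dosages),
    traits,
    tibble::tibble(smoking = smoking, family_history = family_history,
                   oc_use = oc_use, bp_treatment = bp_treatment,
                   glucose_med = glucose_med, t1dm_diag = t1dm_diag,
                   t2dm_diag = t2dm_diag, agatston = 0),
    mets,
    tibble::tibble(attended_6y = attended_6y, attended_7y = attended_7y,
                   attended_10y = attended_10y),
    fu10,
    tibble::tibble(imt_6y = imt_6y, dist_6y = dist_6y, agatston_7y = agatston_7y),
    flags
  )
  attr(out, "params") <- params
  out
}
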