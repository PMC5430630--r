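# Covariate tiers for the incident-outcome models.
#
# Model 1: unadjusted.
# Model 2: + all baseline cardiometabolic risk factors (age, LDL, HDL,
#   triglycerides, systolic/diastolic BP, CRP, glucose, insulin, BMI, waist,
#   daily smoking, family history of CAD; sex excluded in sex-stratified fits;
#   CRP, triglycerides and insulin are log-transformed as skewed covariates).
# Model 3: + log SHBG, and oral-contraceptive use in women.
tier_covariates <- function(tier, stratum) {
  base <- c("age", "ldl", "hdl", "ln_tg", "sbp", "dbp", "ln_crp", "glucose",
            "ln_insulin", "bmi", "waist", "smoking", "family_history")
  covs <- switch(as.character(tier),
                 "1" = character(),
                 "2" = base,
                 "3" = c(base, "ln_shbg", if (stratum == "women") "oc_use"),
                 abort("model tier must be 1, 2 or 3"))
  covs
}

#' Fit one incident-outcome logistic model
#'
#' Maximum-likelihood logistic regression of an incident outcome on SD-scaled
#' log baseline hArg within one sex stratum, at one of three adjustment
#' tiers: unadjusted (1), plus all baseline cardiometabolic risk factors (2),
#' plus SHBG and oral-contraceptive use in women (3). Skewed covariates
#' (CRP, triglycerides, insulin, SHBG) are log-transformed. The at-risk data
#' should come from [incident_risk_set()]: participants free of the
#' condition at baseline with an observed follow-up flag.
#'
#' @param data At-risk rows for one stratum: cohort columns plus the 0/1
#'   outcome column.
#' @param outcome Name of the binary outcome column.
#' @param exposure Exposure column; values must be positive (log-SD-scaled
#'   internally) unless `exposure_is_scaled = TRUE`, in which case the
#'   column is used as-is (e.g. an already-binary or pre-scaled exposure).
#' @param tier Adjustment tier 1, 2 or 3.
#' @param stratum `"men"` or `"women"` (controls the contraceptive
#'   covariate); `"all"` fits unstratified.
#' @param exposure_is_scaled Skip the internal log-SD scaling.
#'
#' @return An object of class `"harg_incident"`: list with `or`, `conf_low`,
#'   `conf_high` (Wald 95% CI on the odds-ratio scale), `p`, `log_or`, `se`,
#'   `n_at_risk`, `n_incident`, `converged`, `separation` flag, `tier`,
#'   `stratum`, `outcome`, and the underlying `fit`.
#' @export
fit_incident_model <- function(data, outcome, exposure = "harg", tier = 1,
                               stratum = c("men", "women", "all"),
                               exposure_is_scaled = FALSE) {
  stratum <- match.arg(stratum)
  assert_that(outcome %in% names(data), "outcome column not found")
  y <- data[[outcome]]
  d <- data[!is.na(y), , drop = FALSE]
  y <- y[!is.na(y)]
  n_at_risk <- length(y)
  n_incident <- sum(y == 1)
  if (n_incident == 0) abort("no events", class = "homarg_no_events")
  if (n_incident == n_at_risk) abort("all at-risk participants had events")

  d$.expo <- if (exposure_is_scaled) d[[exposure]] else scale_ln(d[[exposure]])
  d$ln_tg <- if ("tg" %in% names(d)) log(d$tg) else NULL
  d$ln_crp <- if ("crp" %in% names(d)) log(d$crp) else NULL
  d$ln_insulin <- if ("insulin" %in% names(d)) log(d$insulin) else NULL
  d$ln_shbg <- if ("shbg" %in% names(d)) log(d$shbg) else NULL

  covs <- tier_covariates(tier, stratum)
  covs <- intersect(covs, names(d))
  if (tier >= 2) {
    cc <- suppressWarnings(stats::cor(d$bmi, d$waist, use = "complete.obs"))
    if (!is.na(cc) && abs(cc) > 0.9) {
      warn("BMI and waist circumference are highly collinear in this stratum")
    }
  }
  rhs <- paste(c(".expo", covs), collapse = " + ")
  fit <- glm(as.formula(paste0("`", outcome, "` ~ ", rhs)),
             family = binomial(), data = d)
  s <- summary(fit)$coefficients
  b <- s[".expo", 1]
  se <- s[".expo", 2]

  # quasi-complete separation heuristic: runaway coefficient or SE
  separation <- !fit$converged || abs(b) > 10 || se > 10
  if (separation) warn("possible quasi-complete separation; estimate unstable")

  structure(
    list(or = exp(b), conf_low = exp(b - qnorm(0.975) * se),
         conf_high = exp(b + qnorm(0.975) * se),
         p = s[".expo", 4], log_or = b, se = se,
         n_at_risk = n_at_risk, n_incident = n_incident,
         converged = fit$converged, separation = separation,
         tier = tier, stratum = stratum, outcome = outcome, fit = fit),
    class = "harg_incident"
  )
}

#' @export
print.harg_incident <- function(x, ...) {
  cat(sprintf("Incident %s, %s, model %d: OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$outcome, x$stratum, x$tier, x$or, x$conf_low, x$conf_high, x$p))
  cat(sprintf("  %d incident / %d at risk\n", x$n_incident, x$n_at_risk))
  invisible(x)
}

#' Fit the full outcome x model-tier x sex grid of incident models
#'
#' Builds per-outcome risk sets from baseline and follow-up flags, then fits
#' [fit_incident_model()] for every outcome, adjustment tier and sex
#' stratum. Per-cell failures (e.g. no events) are annotated as missing
#' cells rather than aborting the grid.
#'
#' @param cohort Cohort tibble (baseline covariates + exposure).
#' @param baseline_flags,followup_flags Flag tibbles from
#'   [classify_records()].
#' @param outcomes Outcome flag columns to model (default: all shared flag
#'   columns).
#' @param tiers Model tiers to fit (default `1:3`).
#' @param strata Sex strata (default men and women).
#' @inheritParams fit_incident_model
#'
#' @return A tibble of class `"harg_incident_grid"`: one row per cell with
#'   `outcome, stratum, tier, or, conf_low, conf_high, p, n_at_risk,
#'   n_incident, note` (`note` holds the error message for failed cells).
#' @export
run_model_grid <- function(cohort, baseline_flags, followup_flags,
                           outcomes = NULL, tiers = 1:3,
                           strata = c("men", "women"), exposure = "harg") {
  risk <- incident_risk_set(baseline_flags, followup_flags, outcomes)
  outcomes <- unique(risk$outcome)
  grid <- tidyr::expand_grid(outcome = outcomes, stratum = strata, tier = tiers)

  res <- purrr::pmap_dfr(grid, function(outcome, stratum, tier) {
    ids <- risk$id[risk$outcome == outcome]
    inc <- risk$incident[risk$outcome == outcome]
    d <- dplyr::inner_join(cohort,
                           tibble::tibble(id = ids, .incident = inc),
                           by = "id")
    d <- dplyr::filter(d, .data$sex == ifelse(stratum == "men", "male", "female"))
    cell <- tibble::tibble(outcome = outcome, stratum = stratum, tier = tier,
                           or = NA_real_, conf_low = NA_real_,
                           conf_high = NA_real_, p = NA_real_,
                           n_at_risk = nrow(d),
                           n_incident = sum(d$.incident == 1, na.rm = TRUE),
                           note = NA_character_)
    out <- tryCatch(
      fit_incident_model(d, ".incident", exposure = exposure, tier = tier,
                         stratum = stratum),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      cell$note <- conditionMessage(out)
    } else {
      cell$or <- out$or; cell$conf_low <- out$conf_low
      cell$conf_high <- out$conf_high; cell$p <- out$p
      cell$n_at_risk <- out$n_at_risk; cell$n_incident <- out$n_incident
    }
    cell
  })
  class(res) <- c("harg_incident_grid", class(res))
  res
}
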