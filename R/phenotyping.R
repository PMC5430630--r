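#' Percentile reference cuts by stratum
#'
#' Computes empirical percentile cut values of a variable within strata
#' (sex, optionally crossed with age bands), for use in percentile-based
#' outcome definitions such as high fasting insulin (>90th percentile,
#' sex-specific) or high-risk carotid intima-media thickness (age- and
#' sex-specific >=90th percentile).
#'
#' @param data Tibble with at least `sex` and the target variable.
#' @param var Name of the variable (string).
#' @param prob Percentile as a probability, e.g. `0.9`.
#' @param age_bin_width Optional width (years) of age bands; when supplied,
#'   `data` must contain `age` and cuts are computed per sex x age-band.
#' @param type Quantile definition passed to [stats::quantile()]
#'   (default 7, linear interpolation of the empirical CDF).
#'
#' @return A tibble with columns `sex`, optionally `age_band`, `variable`,
#'   `prob`, `cut`, `quantile_type`. Cut values are monotone in `prob`
#'   within a stratum by construction.
#' @export
percentile_reference <- function(data, var, prob, age_bin_width = NULL, type = 7) {
  assert_that(var %in% names(data), sprintf("column '%s' not found", var))
  assert_that(is_proportion(prob), "prob must be in [0, 1]")
  d <- dplyr::filter(data, !is.na(.data[[var]]), !is.na(.data$sex))
  if (!is.null(age_bin_width)) {
    assert_that("age" %in% names(data), "age column required for age-banded cuts")
    d <- dplyr::mutate(d, age_band = floor(.data$age / age_bin_width) * age_bin_width)
    groups <- c("sex", "age_band")
  } else {
    groups <- "sex"
  }
  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n = dplyr::n(),
      cut = quantile(.data[[var]], probs = prob, type = type, names = FALSE),
      .groups = "drop"
    )
  if (any(out$n < 1) || nrow(out) == 0) abort("empty stratum in percentile reference")
  out |>
    dplyr::mutate(variable = var, prob = prob, quantile_type = type) |>
    dplyr::select(dplyr::all_of(groups), "variable", "prob", "cut",
                  "quantile_type", "n")
}

#' Sex-specific 90th-percentile insulin reference
#'
#' High insulin is defined from follow-up fasting insulin strictly above the
#' sex-specific 90th percentile. This wrapper computes those cuts; each sex
#' stratum must contribute at least 10 non-missing values.
#'
#' @param data Tibble with `sex` and the insulin column.
#' @param var Insulin column name (default `"insulin_10y"`).
#' @inheritParams percentile_reference
#' @return A percentile-reference tibble (see [percentile_reference()]).
#' @export
high_insulin_reference <- function(data, var = "insulin_10y", type = 7) {
  ref <- percentile_reference(data, var, prob = 0.9, type = type)
  if (any(ref$n < 10) || !all(c("male", "female") %in% ref$sex)) {
    abort("each sex stratum needs at least 10 non-missing insulin values")
  }
  ref
}

ref_lookup <- function(refs, variable, sex, age = NULL) {
  if (is.null(refs)) return(rep(NA_real_, length(sex)))
  r <- refs[refs$variable == variable, , drop = FALSE]
  if (nrow(r) == 0) return(rep(NA_real_, length(sex)))
  if ("age_band" %in% names(r) && !all(is.na(r$age_band))) {
    width <- diff(sort(unique(r$age_band)))
    width <- if (length(width)) min(width) else 1
    band <- floor(age / width) * width
    key <- paste(sex, band)
    cuts <- setNames(r$cut, paste(r$sex, r$age_band))
    unname(cuts[key])
  } else {
    cuts <- setNames(r$cut, r$sex)
    unname(cuts[sex])
  }
}

#' Classify records into prevalent/incident outcome flags
#'
#' Deterministic rule engine turning trait values into binary outcome flags
#' using harmonized metabolic-syndrome criteria and related definitions:
#'
#' * `abdominal_obesity`: waist >= 102 cm (men) / >= 88 cm (women);
#' * `hypertriglyceridemia`: triglycerides > 1.7 mmol/L;
#' * `low_hdl`: HDL < 1.0 mmol/L (men) / < 1.3 mmol/L (women);
#' * `high_bp`: systolic >= 130 mmHg or diastolic >= 85 mmHg or
#'   antihypertensive treatment (treatment alone suffices when pressures are
#'   missing; a message notes when this rule fires);
#' * `hyperglycaemia`: fasting glucose >= 5.6 mmol/L or previously diagnosed
#'   type 2 diabetes;
#' * `obesity`: BMI >= 30 kg/m^2;
#' * `high_insulin`: insulin strictly above the sex-specific 90th-percentile
#'   cut supplied in `refs`;
#' * `t2dm`: fasting glucose >= 7.0 mmol/L, or HbA1c >= 6.5%, or
#'   glucose-lowering medication without reported type 1 diabetes, or
#'   physician-diagnosed type 2 diabetes;
#' * `cac_present`: Agatston score >= 1 (0 means absent);
#' * `high_risk_imt`: IMT at or above the age/sex-specific 90th-percentile cut;
#' * `low_distensibility`: distensibility at or below the age/sex-specific
#'   10th-percentile cut.
#'
#' Missing required inputs yield `NA` flags, never `FALSE`. Column names are
#' remapped through `cols` so the same rules apply to baseline or follow-up
#' measurements.
#'
#' @param data Tibble with `id`, `sex` and trait columns.
#' @param refs Optional percentile-reference tibble (rows for `insulin`,
#'   `imt`, `dist` as needed) from [percentile_reference()].
#' @param cols Named character vector mapping rule inputs (`waist`, `tg`,
#'   `hdl`, `sbp`, `dbp`, `bp_treatment`, `glucose`, `bmi`, `insulin`,
#'   `hba1c`, `glucose_med`, `t1dm_diag`, `t2dm_diag`, `agatston`, `imt`,
#'   `dist`) to columns of `data`. Inputs whose mapped column is absent give
#'   `NA` flags.
#'
#' @return A tibble of `id`, `sex` and integer 0/1/NA flag columns.
#' @export
#' @examples
#' d <- tibble::tibble(id = 1:2, sex = c("male", "female"),
#'                     waist = c(103, 87.9), tg = c(1.8, 1.0),
#'                     hdl = c(0.9, 1.4), sbp = c(128, 131), dbp = c(80, 70),
#'                     bp_treatment = 0, glucose = c(5.6, 5.59), bmi = c(31, 24),
#'                     hba1c = c(5.4, 6.5))
#' classify_records(d)
classify_records <- function(data, refs = NULL, cols = character()) {
  assert_that("sex" %in% names(data), "data must contain a sex column")
  bad_sex <- !data$sex %in% c("male", "female") & !is.na(data$sex)
  if (any(bad_sex)) abort("unknown sex value; expected 'male' or 'female'")

  pick <- function(input) {
    colname <- if (input %in% names(cols)) cols[[input]] else input
    if (colname %in% names(data)) data[[colname]] else rep(NA_real_, nrow(data))
  }
  num <- function(input) {
    x <- pick(input)
    if (is.logical(x)) x <- as.numeric(x)
    x
  }
  conc <- c("waist", "tg", "hdl", "glucose", "insulin", "bmi", "hba1c")
  for (v in conc) {
    if (any(num(v) < 0, na.rm = TRUE)) {
      abort(sprintf("negative values in '%s' are not valid concentrations", v))
    }
  }

  sex <- data$sex
  male <- sex == "male"
  waist <- num("waist"); tg <- num("tg"); hdl <- num("hdl")
  sbp <- num("sbp"); dbp <- num("dbp"); treat <- num("bp_treatment")
  glucose <- num("glucose"); bmi <- num("bmi"); insulin <- num("insulin")
  hba1c <- num("hba1c"); gmed <- num("glucose_med")
  t1d <- num("t1dm_diag"); t2d <- num("t2dm_diag"); agat <- num("agatston")
  imt <- num("imt"); dist <- num("dist")
  age <- if ("age" %in% names(data)) data$age else rep(NA_real_, nrow(data))

  flag <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x))

  abdominal_obesity <- flag(ifelse(male, waist >= 102, waist >= 88))
  hypertriglyceridemia <- flag(tg > 1.7)
  low_hdl <- flag(ifelse(male, hdl < 1.0, hdl < 1.3))

  # BP rule: measured thresholds OR treatment; treatment alone decides when
  # measurements are missing
  bp_measured <- (sbp >= 130) | (dbp >= 85)
  high_bp <- dplyr::case_when(
    !is.na(treat) & treat == 1 ~ 1L,
    !is.na(bp_measured) & bp_measured ~ 1L,
    !is.na(bp_measured) & !bp_measured & !is.na(treat) ~ 0L,
    TRUE ~ NA_integer_
  )
  n_treat_only <- sum(is.na(bp_measured) & treat == 1, na.rm = TRUE)
  if (n_treat_only > 0) {
    inform(sprintf(
      "high_bp set from treatment alone for %d record(s) with missing pressures",
      n_treat_only))
  }

  t2dm <- flag((glucose >= 7.0) %na% FALSE |
                 (hba1c >= 6.5) %na% FALSE |
                 ((gmed == 1) %na% FALSE & !((t1d == 1) %na% FALSE)) |
                 ((t2d == 1) %na% FALSE))
  # all-missing rows stay missing
  t2dm[is.na(glucose) & is.na(hba1c) & is.na(gmed) & is.na(t2d)] <- NA_integer_

  hyperglycaemia <- flag((glucose >= 5.6) | ((t2d == 1) %na% FALSE))
  hyperglycaemia[is.na(glucose) & is.na(t2d)] <- NA_integer_

  obesity <- flag(bmi >= 30)

  ins_cut <- ref_lookup(refs, "insulin", sex, age)
  if (all(is.na(ins_cut)) && !is.null(refs)) {
    # also accept the raw column name used when building the reference
    vars <- unique(refs$variable)
    ins_var <- vars[grepl("insulin", vars)]
    if (length(ins_var) == 1) ins_cut <- ref_lookup(refs, ins_var, sex, age)
  }
  high_insulin <- flag(insulin > ins_cut)

  cac_present <- flag(agat >= 1)

  imt_cut <- ref_lookup(refs, "imt", sex, age)
  high_risk_imt <- flag(imt >= imt_cut)
  dist_cut <- ref_lookup(refs, "dist", sex, age)
  low_distensibility <- flag(dist <= dist_cut)

  tibble::tibble(
    id = if ("id" %in% names(data)) data$id else seq_len(nrow(data)),
    sex = sex,
    abdominal_obesity = abdominal_obesity,
    hypertriglyceridemia = hypertriglyceridemia,
    low_hdl = low_hdl,
    high_bp = high_bp,
    hyperglycaemia = hyperglycaemia,
    obesity = obesity,
    high_insulin = high_insulin,
    t2dm = t2dm,
    cac_present = cac_present,
    high_risk_imt = high_risk_imt,
    low_distensibility = low_distensibility
  )
}

#' Build incident risk sets from baseline and follow-up flags
#'
#' For each outcome, participants with the condition at baseline are excluded;
#' among the remainder, only those with an observed follow-up flag are at
#' risk, and incident cases are the at-risk participants whose follow-up flag
#' is set.
#'
#' @param baseline_flags,followup_flags Flag tibbles from
#'   [classify_records()] (or any tibble with `id` plus 0/1/NA flag columns);
#'   both must cover the same participant ids.
#' @param outcomes Flag columns to process (default: all flag columns present
#'   in both tables).
#'
#' @return A tibble with columns `outcome, id, at_risk, incident`; rows are
#'   restricted to at-risk participants (`at_risk` is always 1, retained for
#'   downstream clarity).
#' @export
incident_risk_set <- function(baseline_flags, followup_flags, outcomes = NULL) {
  assert_that("id" %in% names(baseline_flags) && "id" %in% names(followup_flags),
              "flag tables must contain an id column")
  if (!setequal(baseline_flags$id, followup_flags$id)) {
    abort("baseline and follow-up flag tables cover different participant ids")
  }
  flag_cols <- setdiff(intersect(names(baseline_flags), names(followup_flags)),
                       c("id", "sex"))
  outcomes <- outcomes %||% flag_cols
  assert_that(all(outcomes %in% flag_cols),
              "requested outcomes missing from one of the flag tables")

  purrr::map_dfr(outcomes, function(oc) {
    d <- dplyr::inner_join(
      dplyr::select(baseline_flags, "id", base = dplyr::all_of(oc)),
      dplyr::select(followup_flags, "id", fu = dplyr::all_of(oc)),
      by = "id"
    )
    d <- dplyr::filter(d, !is.na(.data$base), .data$base == 0, !is.na(.data$fu))
    tibble::tibble(outcome = oc, id = d$id, at_risk = 1L,
                   incident = as.integer(d$fu))
  })
}
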