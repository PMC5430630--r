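#' Prepare NMR metabolite columns for association analysis
#'
#' Applies the standard metabolite preparation: zero concentrations are
#' replaced by half the column's minimum positive value (a detection-limit
#' surrogate), columns are natural-log transformed, and each column is
#' centred and scaled to SD 1 either pooled or within sex (sex-specific
#' scaling is used for sex-stratified analyses).
#'
#' @param data Tibble containing the metabolite columns (and `sex` when
#'   `per_sex = TRUE`).
#' @param metabolites Character vector of metabolite column names, or a
#'   tidyselect expression via [dplyr::select()] semantics when passed as
#'   names; defaults to all columns starting with `"met_"`.
#' @param per_sex Scale within sex strata instead of pooled.
#'
#' @return `data` with the metabolite columns replaced by their prepared
#'   values; attributes `"transform"` (`"ln-SD-scaled"`) and
#'   `"scaling_stratum"` record the state.
#' @export
prepare_metabolites <- function(data, metabolites = NULL, per_sex = FALSE) {
  metabolites <- metabolites %||% grep("^met_", names(data), value = TRUE)
  assert_that(length(metabolites) >= 1, "no metabolite columns to prepare")
  assert_that(all(metabolites %in% names(data)), "metabolite columns missing from data")
  if (per_sex) assert_that("sex" %in% names(data), "per-sex scaling needs a sex column")

  for (m in metabolites) {
    x <- data[[m]]
    assert_that(all(x >= 0, na.rm = TRUE),
                sprintf("metabolite '%s' has negative concentrations", m))
    pos <- x[x > 0 & !is.na(x)]
    if (length(pos) == 0) {
      abort(sprintf("metabolite '%s' is entirely zero: no positive minimum exists", m))
    }
    x[x == 0] <- min(pos) / 2
    lx <- log(x)
    if (per_sex) {
      for (s in unique(data$sex)) {
        idx <- which(data$sex == s)
        if (sd(lx[idx], na.rm = TRUE) == 0) {
          abort(sprintf("metabolite '%s' has zero variance in stratum '%s'", m, s))
        }
        lx[idx] <- as.numeric(scale(lx[idx]))
      }
    } else {
      if (sd(lx, na.rm = TRUE) == 0) {
        abort(sprintf("metabolite '%s' has zero variance after log-transform", m))
      }
      lx <- as.numeric(scale(lx))
    }
    data[[m]] <- lx
  }
  attr(data, "transform") <- "ln-SD-scaled"
  attr(data, "scaling_stratum") <- if (per_sex) "per-sex" else "pooled"
  attr(data, "metabolites") <- metabolites
  data
}

#' Effective number of tests and per-test threshold
#'
#' Counts the smallest number of principal components whose cumulative
#' explained variance reaches `variance_target` (computed from the
#' correlation-scale eigendecomposition of the metabolite columns, so the
#' result is invariant to column units), and divides `alpha` by that count.
#' With strongly correlated metabolite panels this gives the
#' multiple-testing threshold `alpha / k`; 25 components explaining over 95%
#' of the variation yields 0.05 / 25 = 0.002.
#'
#' One numerical refinement: components with (numerically) equal eigenvalues
#' span a non-identifiable subspace, so a tied multiplet is never split —
#' if the cut would fall inside a run of equal eigenvalues the whole run is
#' counted. On degenerate low-rank panels (e.g. blocks of duplicated
#' columns) this makes `k` equal the number of distinct blocks; on real
#' data, where eigenvalues are almost surely distinct, it changes nothing.
#'
#' @param data Tibble or matrix of prepared metabolite columns.
#' @param metabolites Metabolite column names (default: columns starting
#'   with `"met_"`, else all numeric columns).
#' @param variance_target Cumulative variance fraction in (0, 1].
#' @param alpha Family-wise alpha to divide.
#'
#' @return A list with `k` (effective number of tests), `threshold`
#'   (`alpha / k`), and `cumulative_variance` (per-component cumulative
#'   explained-variance fractions).
#' @export
#' @examples
#' m <- matrix(rnorm(300), 100, 3)
#' effective_test_threshold(cbind(m, m))  # duplicated blocks count once
effective_test_threshold <- function(data, metabolites = NULL,
                                     variance_target = 0.95, alpha = 0.05) {
  assert_that(is.numeric(variance_target) && variance_target > 0 && variance_target <= 1,
              "variance_target must lie in (0, 1]")
  assert_that(is.numeric(alpha) && alpha > 0 && alpha <= 1,
              "alpha must lie in (0, 1]")
  if (is.matrix(data)) data <- tibble::as_tibble(data, .name_repair = "unique")
  metabolites <- metabolites %||% {
    mm <- grep("^met_", names(data), value = TRUE)
    if (length(mm)) mm else names(data)[vapply(data, is.numeric, logical(1))]
  }
  x <- as.matrix(data[, metabolites, drop = FALSE])
  assert_that(ncol(x) >= 1, "at least one metabolite column is required")
  if (ncol(x) == 1) {
    return(list(k = 1L, threshold = alpha, cumulative_variance = 1))
  }
  sds <- apply(x, 2, sd, na.rm = TRUE)
  assert_that(all(sds > 0), "zero-variance columns cannot enter the correlation matrix")
  cmat <- stats::cor(x, use = "pairwise.complete.obs")
  ev <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cumvar <- cumsum(ev) / sum(ev)
  k <- which(cumvar >= variance_target - 1e-12)[1]
  # never split a tied eigenvalue multiplet (non-identifiable subspace)
  tol <- 1e-8 * max(ev)
  while (k < length(ev) && abs(ev[k + 1] - ev[k]) <= tol) k <- k + 1L
  list(k = as.integer(k), threshold = alpha / k, cumulative_variance = cumvar)
}

# Fit one linear model and pull out the row for `term`; p from the t
# distribution with residual df.
extract_term <- function(fit, term) {
  s <- summary(fit)$coefficients
  if (!term %in% rownames(s)) {
    abort(sprintf("term '%s' dropped from the fit (rank-deficient design?)", term))
  }
  tibble::tibble(beta = s[term, 1], se = s[term, 2],
                 p = s[term, 4], n = length(fit$residuals))
}

check_full_rank <- function(data, vars) {
  mm <- model.matrix(~ ., data = data[, vars, drop = FALSE])
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    abort(paste0("rank-deficient design; collinear terms: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Sex-stratified metabolome-wide association scan
#'
#' For each metabolite and stratum, fits a linear regression with the
#' prepared (log, SD-scaled) metabolite as the outcome and SD-scaled log
#' hArg as the explanatory variable, adjusted for the supplied covariates
#' (oral-contraceptive use enters only in women). Betas are in SD units of
#' metabolite per 1-SD increment in log hArg; p-values use the t
#' distribution with residual degrees of freedom and are flagged against the
#' effective-tests threshold.
#'
#' @param data Cohort tibble; metabolite columns must already be prepared
#'   with [prepare_metabolites()] (matching `stratify_by_sex`).
#' @param metabolites Metabolite column names (default `"met_"` columns).
#' @param exposure hArg column name (raw scale; log-SD-scaled internally
#'   within each stratum).
#' @param covariates Covariate column names; defaults to age, BMI, daily
#'   smoking and log SHBG-style adjustment set
#'   `c("age", "bmi", "smoking", "shbg", "oc_use")`. `oc_use` is kept only
#'   in the women stratum; `shbg` is log-transformed when positive.
#' @param stratify_by_sex Fit separately in men and women (default) or
#'   pooled (`stratum = "all"`).
#' @param threshold Per-test significance threshold used for the `sig`
#'   column (e.g. from [effective_test_threshold()]).
#'
#' @return A tibble of class `"harg_scan"`: one row per metabolite x
#'   stratum with `beta, se, p, n, sig, covariates`.
#' @export
metabolome_scan <- function(data, metabolites = NULL, exposure = "harg",
                            covariates = c("age", "bmi", "smoking", "shbg", "oc_use"),
                            stratify_by_sex = TRUE, threshold = 0.002) {
  metabolites <- metabolites %||% grep("^met_", names(data), value = TRUE)
  assert_that(length(metabolites) >= 1, "no metabolite columns to scan")
  covariates <- intersect(covariates, names(data))

  strata <- if (stratify_by_sex) c("male", "female") else "all"
  res <- purrr::map_dfr(strata, function(s) {
    d <- if (s == "all") data else dplyr::filter(data, .data$sex == s)
    if (nrow(d) == 0) return(NULL)
    covs <- covariates
    if (s != "female") covs <- setdiff(covs, "oc_use")
    if ("shbg" %in% covs && all(d$shbg > 0, na.rm = TRUE)) {
      d$shbg <- log(d$shbg)
    }
    d$.z_harg <- scale_ln(d[[exposure]])
    if (length(covs)) check_full_rank(d, c(".z_harg", covs))
    rhs <- paste(c(".z_harg", covs), collapse = " + ")
    purrr::map_dfr(metabolites, function(m) {
      fit <- lm(as.formula(paste0("`", m, "` ~ ", rhs)), data = d)
      out <- extract_term(fit, ".z_harg")
      out$metabolite <- m
      out$stratum <- if (s == "all") "all" else ifelse(s == "male", "men", "women")
      out
    })
  })
  res <- res |>
    dplyr::mutate(sig = .data$p < threshold,
                  covariates = paste(covariates, collapse = "+")) |>
    dplyr::select("metabolite", "stratum", "beta", "se", "p", "n", "sig", "covariates")
  class(res) <- c("harg_scan", class(res))
  attr(res, "threshold") <- threshold
  res
}

#' Z-test for sex differences in association estimates
#'
#' Compares two stratum-specific estimates for the same metabolite with the
#' Z-statistic `Z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)` and a
#' two-sided normal p-value.
#'
#' @param beta_m,se_m,beta_f,se_f Estimates and standard errors
#'   (vectorised).
#' @return A tibble with columns `z` and `p`.
#' @export
#' @examples
#' sex_difference_z(0.3, 0.1, 0, 0.1)
sex_difference_z <- function(beta_m, se_m, beta_f, se_f) {
  assert_that(all(se_m > 0) && all(se_f > 0), "standard errors must be positive")
  z <- (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' @describeIn sex_difference_z Apply the Z-test to a scan result: joins the
#'   men and women rows of a `"harg_scan"` tibble per metabolite.
#' @param scan A `"harg_scan"` result containing `men` and `women` strata.
#' @export
scan_sex_differences <- function(scan) {
  wide <- scan |>
    dplyr::filter(.data$stratum %in% c("men", "women")) |>
    dplyr::select("metabolite", "stratum", "beta", "se") |>
    tidyr::pivot_wider(names_from = "stratum", values_from = c("beta", "se"))
  dplyr::bind_cols(
    dplyr::select(wide, "metabolite"),
    sex_difference_z(wide$beta_men, wide$se_men, wide$beta_women, wide$se_women)
  )
}

#' BMI-interaction test in the metabolite regressions
#'
#' Adds an hArg x BMI product term to the stratified metabolite regression
#' and reports its coefficient, standard error and p-value, judged against
#' the effective-tests threshold.
#'
#' @inheritParams metabolome_scan
#' @return A tibble with one row per metabolite x stratum:
#'   `interaction_beta, interaction_se, interaction_p, n, sig`.
#' @export
bmi_interaction <- function(data, metabolites = NULL, exposure = "harg",
                            covariates = c("age", "smoking", "shbg", "oc_use"),
                            stratify_by_sex = TRUE, threshold = 0.002) {
  metabolites <- metabolites %||% grep("^met_", names(data), value = TRUE)
  covariates <- setdiff(intersect(covariates, names(data)), "bmi")
  strata <- if (stratify_by_sex) c("male", "female") else "all"
  res <- purrr::map_dfr(strata, function(s) {
    d <- if (s == "all") data else dplyr::filter(data, .data$sex == s)
    if (nrow(d) == 0) return(NULL)
    covs <- covariates
    if (s != "female") covs <- setdiff(covs, "oc_use")
    if ("shbg" %in% covs && all(d$shbg > 0, na.rm = TRUE)) d$shbg <- log(d$shbg)
    d$.z_harg <- scale_ln(d[[exposure]])
    rhs <- paste(c(".z_harg * bmi", covs), collapse = " + ")
    purrr::map_dfr(metabolites, function(m) {
      fit <- lm(as.formula(paste0("`", m, "` ~ ", rhs)), data = d)
      out <- extract_term(fit, ".z_harg:bmi")
      tibble::tibble(metabolite = m,
                     stratum = if (s == "all") "all" else ifelse(s == "male", "men", "women"),
                     interaction_beta = out$beta, interaction_se = out$se,
                     interaction_p = out$p, n = out$n,
                     sig = out$p < threshold)
    })
  })
  res
}
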