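#' Instrument strength F-statistic
#'
#' Single-variant instrument strength from summary statistics:
#' `F = (beta / se)^2`. Instruments with `F < 10` are conventionally flagged
#' as weak.
#'
#' @param beta,se SNP-exposure effect and standard error (vectorised).
#' @return A tibble with columns `f_statistic` and `weak` (logical).
#' @export
#' @examples
#' f_statistic(0.2, 0.02)  # F = 100
f_statistic <- function(beta, se) {
  assert_that(all(se > 0), "standard errors must be positive")
  f <- (beta / se)^2
  tibble::tibble(f_statistic = f, weak = f < 10)
}

NUC_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) NUC_COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns SNP-outcome rows to the exposure's effect allele. Matching
#' effect/other alleles are kept unchanged; swapped alleles flip the sign of
#' the outcome beta; strand-complement matches are relabelled (and flipped
#' when also swapped). Palindromic variants (A/T or G/C) are strand-ambiguous:
#' they are resolved by effect-allele frequency when both tables supply it
#' (frequencies on the same side of 0.5, neither within `eaf_tolerance` of
#' 0.5), otherwise dropped with reason `"ambiguous strand"`. Variants absent
#' from either table, or with irreconcilable alleles, are dropped with a
#' reason. Dropped variants are reported via a message and kept in the
#' `dropped` attribute.
#'
#' @param exposure,outcome Summary-statistics tibbles in the package dialect
#'   (`rsid, effect_allele, other_allele, beta, se, pvalue, n`, optional
#'   `eaf`).
#' @param eaf_tolerance Palindromic variants with frequency within this
#'   distance of 0.5 are considered unresolvable (default 0.08).
#'
#' @return A tibble of class `"harg_harmonized"`: per retained SNP `rsid,
#'   effect_allele, other_allele, beta_x, se_x, beta_y, se_y, weight`
#'   (first-order weight `1/se_y^2`), `ratio` (`beta_y/beta_x`), `ratio_se`
#'   (`se_y/|beta_x|`), `action` (`"kept"` or `"flipped"`). Attribute
#'   `"dropped"` lists removed SNPs and reasons.
#' @export
harmonize <- function(exposure, outcome, eaf_tolerance = 0.08) {
  need <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  assert_that(all(need %in% names(exposure)) && all(need %in% names(outcome)),
              "summary tables need rsid, effect_allele, other_allele, beta, se")
  dropped <- tibble::tibble(rsid = character(), reason = character())
  drop_row <- function(rsid, reason) {
    dropped <<- dplyr::bind_rows(dropped, tibble::tibble(rsid = rsid, reason = reason))
  }
  only_x <- setdiff(exposure$rsid, outcome$rsid)
  if (length(only_x)) drop_row(only_x, "absent from outcome table")
  only_y <- setdiff(outcome$rsid, exposure$rsid)
  if (length(only_y)) drop_row(only_y, "absent from exposure table")

  m <- dplyr::inner_join(exposure, outcome, by = "rsid",
                         suffix = c("_x", "_y"))
  rows <- purrr::pmap_dfr(m, function(...) {
    r <- list(...)
    a1x <- toupper(r$effect_allele_x); a2x <- toupper(r$other_allele_x)
    a1y <- toupper(r$effect_allele_y); a2y <- toupper(r$other_allele_y)
    pal <- is_palindromic(a1x, a2x)

    orient <- if (a1y == a1x && a2y == a2x) {
      "same"
    } else if (a1y == a2x && a2y == a1x) {
      "swapped"
    } else if (!pal && a1y == NUC_COMPLEMENT[a1x] && a2y == NUC_COMPLEMENT[a2x]) {
      "same"     # strand flip only
    } else if (!pal && a1y == NUC_COMPLEMENT[a2x] && a2y == NUC_COMPLEMENT[a1x]) {
      "swapped"  # strand flip + swap
    } else {
      NA_character_
    }
    if (is.na(orient)) {
      drop_row(r$rsid, "allele mismatch")
      return(NULL)
    }
    if (pal) {
      eaf_x <- r$eaf_x %||% NA_real_
      eaf_y <- r$eaf_y %||% NA_real_
      if (is.na(eaf_x) || is.na(eaf_y) ||
          abs(eaf_x - 0.5) < eaf_tolerance || abs(eaf_y - 0.5) < eaf_tolerance) {
        drop_row(r$rsid, "ambiguous strand")
        return(NULL)
      }
      # frequencies identify the aligned orientation for palindromic pairs
      eaf_y_aligned <- if (orient == "same") eaf_y else 1 - eaf_y
      if ((eaf_x - 0.5) * (eaf_y_aligned - 0.5) < 0) {
        orient <- if (orient == "same") "swapped" else "same"
      }
    }
    beta_y <- if (orient == "swapped") -r$beta_y else r$beta_y
    tibble::tibble(
      rsid = r$rsid, effect_allele = a1x, other_allele = a2x,
      beta_x = r$beta_x, se_x = r$se_x, beta_y = beta_y, se_y = r$se_y,
      action = if (orient == "swapped") "flipped" else "kept"
    )
  })
  if (nrow(dropped)) {
    inform(paste0("harmonization dropped ", nrow(dropped), " SNP(s): ",
                  paste(dropped$rsid, "(", dropped$reason, ")", collapse = "; ")))
  }
  if (is.null(rows) || nrow(rows) == 0) abort("no usable instruments")
  assert_that(all(rows$se_y > 0) && all(rows$se_x > 0),
              "standard errors must be positive")
  rows <- rows |>
    dplyr::mutate(weight = 1 / .data$se_y^2,
                  ratio = .data$beta_y / .data$beta_x,
                  ratio_se = .data$se_y / abs(.data$beta_x))
  class(rows) <- c("harg_harmonized", class(rows))
  attr(rows, "dropped") <- dropped
  rows
}

#' Per-SNP Wald ratio causal estimate
#'
#' The single-instrument causal estimate `theta_j = beta_y / beta_x` with
#' first-order (delta-method) standard error `se_j = se_y / |beta_x|`.
#'
#' @param beta_x,beta_y SNP-exposure and SNP-outcome effects.
#' @param se_y SNP-outcome standard error.
#' @return A tibble with columns `ratio` and `ratio_se`.
#' @export
#' @examples
#' wald_ratio(0.25, 0.05, 0.01)  # theta 0.2, SE 0.04
wald_ratio <- function(beta_x, beta_y, se_y) {
  assert_that(all(beta_x != 0), "null instrument: beta_x must be non-zero")
  assert_that(all(se_y > 0), "se_y must be positive")
  tibble::tibble(ratio = beta_y / beta_x, ratio_se = se_y / abs(beta_x))
}

#' Combine instruments by inverse-variance weighting
#'
#' Weighted linear regression of the SNP-outcome associations on the
#' SNP-exposure associations through the origin with first-order weights
#' `1/se_y^2`:
#' `theta_hat = sum(beta_x * beta_y / se_y^2) / sum(beta_x^2 / se_y^2)`,
#' with fixed-effects standard error `1/sqrt(sum(beta_x^2 / se_y^2))`.
#' Heterogeneity between the per-SNP ratios is measured by Cochran's Q
#' (`Q = sum(w_j (theta_j - theta_hat)^2)` with `w_j = beta_x^2 / se_y^2`);
#' the multiplicative random-effects model inflates the standard error by
#' the dispersion `phi = max(1, sqrt(Q / (J - 1)))`, keeping the
#' fixed-effects point estimate while never reporting a more precise
#' interval in the presence of heterogeneity. The causal p-value uses the
#' normal distribution with the random-effects SE.
#'
#' When the exposure betas arrive in per-SD units, `scale_factor` (the SD of
#' the exposure, e.g. 0.65 µmol/L for serum hArg) converts the combined
#' estimate to per-unit scale: betas are multiplied by `1/scale_factor`
#' before combination so the estimate reads per 1 µmol/L.
#'
#' @param harmonized A `"harg_harmonized"` tibble (or any tibble with
#'   `beta_x, se_x, beta_y, se_y`).
#' @param exponentiate Report the estimate as an odds ratio (for binary
#'   outcomes whose betas are log odds).
#' @param scale_factor Optional exposure SD for per-SD to per-unit
#'   conversion (default `NULL`, no rescaling).
#'
#' @return An object of class `"harg_ivw"`: list with `estimate` (theta-hat,
#'   identical under fixed and random effects), `se_fixed`, `se_re`,
#'   `conf_low`/`conf_high` (from the random-effects SE), `p`, `q`,
#'   `df = J - 1`, `p_q` (`NA` when `J < 2`), `j`, `phi`, `exponentiated`,
#'   and `or`/`or_low`/`or_high` when `exponentiate = TRUE`.
#' @export
#' @examples
#' h <- tibble::tibble(beta_x = c(1, 1), se_x = 0.1,
#'                     beta_y = c(0.1, 0.3), se_y = c(1, 1))
#' ivw_combine(h)
ivw_combine <- function(harmonized, exponentiate = FALSE, scale_factor = NULL) {
  j <- nrow(harmonized)
  assert_that(!is.null(j) && j >= 1, "at least one instrument is required")
  assert_that(all(harmonized$se_y > 0), "se_y must be positive")
  bx <- harmonized$beta_x
  by <- harmonized$beta_y
  sey <- harmonized$se_y
  assert_that(all(bx != 0), "null instrument: beta_x must be non-zero")
  if (!is.null(scale_factor)) {
    assert_that(scale_factor > 0, "scale_factor must be positive")
    bx <- bx / scale_factor
  }

  w <- bx^2 / sey^2
  theta <- sum(bx * by / sey^2) / sum(bx^2 / sey^2)
  se_fixed <- 1 / sqrt(sum(bx^2 / sey^2))
  ratios <- by / bx
  q <- sum(w * (ratios - theta)^2)
  df <- j - 1L
  phi <- if (j >= 2) max(1, sqrt(q / df)) else 1
  se_re <- phi * se_fixed
  p <- two_sided_p(theta, se_re)
  p_q <- if (j >= 2) pchisq(q, df, lower.tail = FALSE) else NA_real_

  out <- list(estimate = theta, se_fixed = se_fixed, se_re = se_re,
              conf_low = theta - qnorm(0.975) * se_re,
              conf_high = theta + qnorm(0.975) * se_re,
              p = p, q = q, df = df, p_q = p_q, j = j, phi = phi,
              exponentiated = exponentiate)
  if (exponentiate) {
    out$or <- exp(theta)
    out$or_low <- exp(out$conf_low)
    out$or_high <- exp(out$conf_high)
  }
  structure(out, class = "harg_ivw")
}

#' @export
print.harg_ivw <- function(x, ...) {
  if (isTRUE(x$exponentiated)) {
    cat(sprintf("IVW causal estimate: OR %.3f (95%% CI %.3f-%.3f) per 1-unit exposure, p = %.3g\n",
                x$or, x$or_low, x$or_high, x$p))
  } else {
    cat(sprintf("IVW causal estimate: %.4f (95%% CI %.4f to %.4f) per 1-unit exposure, p = %.3g\n",
                x$estimate, x$conf_low, x$conf_high, x$p))
  }
  cat(sprintf("  J = %d instruments; Q = %.3f on %d df (p = %s); dispersion phi = %.3f\n",
              x$j, x$q, x$df,
              ifelse(is.na(x$p_q), "NA", sprintf("%.3g", x$p_q)), x$phi))
  invisible(x)
}

#' Cochran's Q heterogeneity test
#'
#' Tests dissimilarity of the per-SNP causal ratios around the combined
#' estimate: `Q = sum(w_j (theta_j - theta_hat)^2)` with first-order weights
#' `w_j = beta_x^2 / se_y^2`, referred to the chi-square distribution with
#' `J - 1` degrees of freedom.
#'
#' @param harmonized A harmonized tibble with at least two instruments.
#' @param estimate Combined estimate; defaults to the IVW estimate of
#'   `harmonized`.
#' @return A tibble with `q`, `df`, `p_q`.
#' @export
cochran_q <- function(harmonized, estimate = NULL) {
  j <- nrow(harmonized)
  if (is.null(j) || j < 2) abort("heterogeneity undefined: at least 2 instruments required")
  estimate <- estimate %||% ivw_combine(harmonized)$estimate
  w <- harmonized$beta_x^2 / harmonized$se_y^2
  ratios <- harmonized$beta_y / harmonized$beta_x
  q <- sum(w * (ratios - estimate)^2)
  tibble::tibble(q = q, df = j - 1L, p_q = pchisq(q, j - 1L, lower.tail = FALSE))
}

#' Run MR across a set of outcomes
#'
#' Iterates harmonization and IVW combination of one exposure against many
#' outcome summary tables, assembling a forest-table-ready long format.
#' Per-outcome failures (e.g. no usable instruments) are annotated in the
#' `note` column and the grid completes.
#'
#' @param exposure Exposure summary-statistics tibble.
#' @param outcomes Named list of outcome summary-statistics tibbles.
#' @param exponentiate Logical (recycled over outcomes): report odds ratios.
#' @param scale_factor Passed to [ivw_combine()].
#'
#' @return A tibble of class `"harg_mr_grid"`: one row per outcome with
#'   `outcome, j, estimate, se, conf_low, conf_high, p, q, df, p_q, phi,
#'   note`.
#' @export
mr_grid <- function(exposure, outcomes, exponentiate = FALSE, scale_factor = NULL) {
  assert_that(length(outcomes) >= 1, "at least one outcome table is required")
  nm <- names(outcomes) %||% paste0("outcome_", seq_along(outcomes))
  exponentiate <- rep_len(exponentiate, length(outcomes))
  res <- purrr::map_dfr(seq_along(outcomes), function(i) {
    cell <- tibble::tibble(outcome = nm[i], j = NA_integer_,
                           estimate = NA_real_, se = NA_real_,
                           conf_low = NA_real_, conf_high = NA_real_,
                           p = NA_real_, q = NA_real_, df = NA_integer_,
                           p_q = NA_real_, phi = NA_real_, note = NA_character_)
    out <- tryCatch({
      h <- suppressMessages(harmonize(exposure, outcomes[[i]]))
      ivw_combine(h, exponentiate = exponentiate[i], scale_factor = scale_factor)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      cell$note <- conditionMessage(out)
    } else {
      cell$j <- out$j; cell$estimate <- out$estimate; cell$se <- out$se_re
      cell$conf_low <- out$conf_low; cell$conf_high <- out$conf_high
      cell$p <- out$p; cell$q <- out$q; cell$df <- out$df
      cell$p_q <- out$p_q; cell$phi <- out$phi
    }
    cell
  })
  class(res) <- c("harg_mr_grid", class(res))
  res
}
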