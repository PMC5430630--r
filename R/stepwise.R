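#' Bidirectional stepwise-AIC determinants model
#'
#' Identifies the independent determinants of (log) serum hArg by
#' bidirectional stepwise linear-model selection under Akaike's information
#' criterion, starting from the full candidate model (the behaviour of
#' `MASS::stepAIC` with default settings, which this wraps). At each step
#' every single-term addition and deletion is evaluated and the move with
#' the lowest AIC applied; the search stops when no move lowers AIC, so the
#' returned model is a local optimum of the add/drop neighbourhood. Ties in
#' AIC resolve toward the smaller model (deletions are considered first).
#'
#' Perfectly collinear candidates are dropped with a warning before the
#' search. Complete cases only.
#'
#' @param data Tibble with the response and candidate columns.
#' @param response Response column name (e.g. log hArg).
#' @param candidates Character vector of candidate predictor columns; may
#'   include SNP dosage columns.
#' @param start Start from the `"full"` model (default) or `"intercept"`.
#'
#' @return An object of class `"harg_stepwise"`: a list with the selected
#'   `fit` (an `lm`), `terms`, a `coefficients` tibble (estimate, 95% CI,
#'   p-value), `r_squared`, `aic`, and the AICs of the full and
#'   intercept-only models.
#' @export
#' @examples
#' d <- tibble::tibble(y = rnorm(50), x1 = rnorm(50), x2 = rnorm(50))
#' d$y <- 2 * d$x1 + rnorm(50, sd = 0.01)
#' stepwise_determinants(d, "y", c("x1", "x2"))
stepwise_determinants <- function(data, response, candidates, start = c("full", "intercept")) {
  start <- match.arg(start)
  assert_that(response %in% names(data), "response column not found")
  assert_that(all(candidates %in% names(data)), "candidate columns missing from data")
  d <- data[stats::complete.cases(data[, c(response, candidates), drop = FALSE]),
            c(response, candidates), drop = FALSE]
  assert_that(nrow(d) > length(candidates) + 2, "too few complete cases for selection")

  # drop perfectly collinear candidates before the search
  if (length(candidates)) {
    mm <- model.matrix(~ ., data = d[, candidates, drop = FALSE])
    q <- qr(mm)
    if (q$rank < ncol(mm)) {
      bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
      keep <- setdiff(candidates, bad)
      warn(paste0("dropping perfectly collinear candidate(s): ",
                  paste(bad, collapse = ", ")))
      candidates <- keep
    }
  }

  fml_full <- if (length(candidates)) {
    as.formula(paste(response, "~", paste(candidates, collapse = " + ")))
  } else {
    as.formula(paste(response, "~ 1"))
  }
  fml_null <- as.formula(paste(response, "~ 1"))
  fit_full <- lm(fml_full, data = d)
  fit_null <- lm(fml_null, data = d)

  fit0 <- if (start == "full") fit_full else fit_null
  fit <- if (length(candidates)) {
    MASS::stepAIC(fit0, scope = list(lower = fml_null, upper = fml_full),
                  direction = "both", trace = 0)
  } else {
    fit_null
  }

  terms_sel <- attr(stats::terms(fit), "term.labels")
  cf <- summary(fit)$coefficients
  ci <- confint(fit)
  coef_tbl <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]), se = unname(cf[, 2]),
    conf_low = unname(ci[, 1]), conf_high = unname(ci[, 2]),
    p = unname(cf[, 4])
  )

  structure(
    list(fit = fit, terms = terms_sel, coefficients = coef_tbl,
         r_squared = summary(fit)$r.squared,
         aic = AIC(fit), aic_full = AIC(fit_full), aic_null = AIC(fit_null),
         n = nrow(d), response = response, candidates = candidates),
    class = "harg_stepwise"
  )
}

#' @export
print.harg_stepwise <- function(x, ...) {
  cat("Bidirectional stepwise-AIC model for", x$response,
      sprintf("(n = %d)\n", x$n))
  cat(sprintf("Selected %d of %d candidates; AIC %.2f (full %.2f, intercept %.2f); R^2 %.3f\n",
              length(x$terms), length(x$candidates), x$aic, x$aic_full,
              x$aic_null, x$r_squared))
  print(x$coefficients)
  invisible(x)
}
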