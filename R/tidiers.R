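# broom-style tidiers for the package's fitted objects.

#' Tidy an IVW causal estimate
#'
#' @param x A `"harg_ivw"` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate, se_fixed, se_re, conf_low, conf_high,
#'   p` (plus `or, or_low, or_high` for exponentiated fits).
#' @method tidy harg_ivw
#' @export
tidy.harg_ivw <- function(x, ...) {
  out <- tibble::tibble(estimate = x$estimate, se_fixed = x$se_fixed,
                        se_re = x$se_re, conf_low = x$conf_low,
                        conf_high = x$conf_high, p = x$p)
  if (isTRUE(x$exponentiated)) {
    out$or <- x$or; out$or_low <- x$or_low; out$or_high <- x$or_high
  }
  out
}

#' Model-level summary of an IVW fit
#'
#' @inheritParams tidy.harg_ivw
#' @return One-row tibble: `j, q, df, p_q, phi`.
#' @method glance harg_ivw
#' @export
glance.harg_ivw <- function(x, ...) {
  tibble::tibble(j = x$j, q = x$q, df = x$df, p_q = x$p_q, phi = x$phi)
}

#' Tidy an incident-outcome logistic fit
#'
#' @param x A `"harg_incident"` object.
#' @param ... Unused.
#' @return One-row tibble with the OR, Wald 95% CI, p-value and counts.
#' @method tidy harg_incident
#' @export
tidy.harg_incident <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, stratum = x$stratum, tier = x$tier,
                 or = x$or, conf_low = x$conf_low, conf_high = x$conf_high,
                 p = x$p, n_at_risk = x$n_at_risk, n_incident = x$n_incident)
}

#' @rdname tidy.harg_incident
#' @method glance harg_incident
#' @export
glance.harg_incident <- function(x, ...) {
  tibble::tibble(converged = x$converged, separation = x$separation,
                 n_at_risk = x$n_at_risk, n_incident = x$n_incident)
}

#' Tidy a stepwise-AIC determinants model
#'
#' @param x A `"harg_stepwise"` object.
#' @param ... Unused.
#' @return The coefficient tibble (term, estimate, 95% CI, p).
#' @method tidy harg_stepwise
#' @export
tidy.harg_stepwise <- function(x, ...) x$coefficients

#' @rdname tidy.harg_stepwise
#' @method glance harg_stepwise
#' @export
glance.harg_stepwise <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, aic = x$aic, aic_full = x$aic_full,
                 aic_null = x$aic_null, n_terms = length(x$terms), n = x$n)
}
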