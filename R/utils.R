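# Internal helpers shared across modules.

# Stop with a parameter error unless `cond` is a single TRUE.
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "homarg_parameter_error")
  invisible(TRUE)
}

is_proportion <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

# Natural-log transform followed by SD scaling (mean 0, SD 1).
# Values must be strictly positive.
scale_ln <- function(x) {
  assert_that(all(x > 0, na.rm = TRUE), "values must be positive before log-transform")
  as.numeric(scale(log(x)))
}

# SD-scale log hArg within strata (a factor/character vector), returning a
# numeric vector aligned with `x`. NA strata yield NA.
scale_ln_by <- function(x, stratum) {
  out <- rep(NA_real_, length(x))
  for (s in unique(stratum[!is.na(stratum)])) {
    idx <- which(stratum == s & !is.na(x))
    out[idx] <- as.numeric(scale(log(x[idx])))
  }
  out
}

# Two-sided normal p-value for an estimate/SE pair.
two_sided_p <- function(est, se) 2 * pnorm(-abs(est / se))

`%na%` <- function(a, b) ifelse(is.na(a), b, a)
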