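test_that("unadjusted binary-exposure OR equals the 2x2 cross-product ratio", {
  d <- binary_exposure_fixture()
  fit <- fit_incident_model(d, "event", exposure = "exposed", tier = 1,
                            stratum = "men", exposure_is_scaled = TRUE)
  # (20 * 90) / (80 * 10) = 2.25
  expect_equal(fit$or, 2.25, tolerance = 1e-6)
  expect_identical(fit$n_at_risk, 200L)
  expect_identical(fit$n_incident, 30L)
  expect_true(fit$conf_low < fit$or && fit$or < fit$conf_high)
})

test_that("a null exposure gives OR near 1 with a covering interval", {
  set.seed(5)
  n <- 4000
  d <- tibble::tibble(sex = "male", harg = exp(rnorm(n, 0.56, 0.34)),
                      event = rbinom(n, 1, 0.1))
  fit <- fit_incident_model(d, "event", tier = 1, stratum = "men")
  expect_lt(fit$conf_low, 1)
  expect_gt(fit$conf_high, 1)
})

test_that("the OR per SD is invariant to rescaling the raw exposure", {
  set.seed(7)
  n <- 1000
  d <- tibble::tibble(sex = "female", harg = exp(rnorm(n, 0.5, 0.3)),
                      event = rbinom(n, 1, plogis(-2 + 0.3 * scale(log(exp(rnorm(n)))))))
  d$event <- rbinom(n, 1, plogis(-2 + 0.3 * as.numeric(scale(log(d$harg)))))
  f1 <- fit_incident_model(d, "event", tier = 1, stratum = "women")
  d2 <- dplyr::mutate(d, harg = 2 * harg)
  f2 <- fit_incident_model(d2, "event", tier = 1, stratum = "women")
  expect_equal(f1$or, f2$or, tolerance = 1e-10)
})

test_that("a planted OR of 1.5 per SD is recovered in expectation", {
  logors <- vapply(1:60, function(i) {
    set.seed(100 + i)
    n <- 2000
    d <- tibble::tibble(sex = "male", harg = exp(rnorm(n, 0.56, 0.34)))
    z <- as.numeric(scale(log(d$harg)))
    d$event <- rbinom(n, 1, plogis(qlogis(0.12) + log(1.5) * z))
    fit_incident_model(d, "event", tier = 1, stratum = "men")$log_or
  }, numeric(1))
  mc_se <- sd(logors) / sqrt(length(logors))
  expect_lt(abs(mean(logors) - log(1.5)), 3 * mc_se)
})

test_that("model tiers nest and the contraceptive covariate is women-only", {
  co <- generate_cohort(cohort_params(n_participants = 3000, seed = 43))
  base <- suppressMessages(classify_records(co))
  fu <- suppressMessages(classify_records(
    co, cols = c(waist = "waist_10y", tg = "tg_10y", hdl = "hdl_10y",
                 sbp = "sbp_10y", dbp = "dbp_10y", glucose = "glucose_10y",
                 bmi = "bmi_10y", hba1c = "hba1c_10y")))
  rs <- incident_risk_set(base, fu, outcomes = "obesity")
  d <- dplyr::inner_join(co, tibble::tibble(id = rs$id, inc = rs$incident), by = "id")
  terms_of <- function(stratum, tier) {
    dd <- dplyr::filter(d, sex == ifelse(stratum == "men", "male", "female"))
    f <- fit_incident_model(dd, "inc", tier = tier, stratum = stratum)
    attr(stats::terms(f$fit), "term.labels")
  }
  t1 <- terms_of("men", 1); t2 <- terms_of("men", 2); t3 <- terms_of("men", 3)
  expect_true(all(t1 %in% t2))
  expect_true(all(t2 %in% t3))
  expect_false("oc_use" %in% t3)
  t3w <- terms_of("women", 3)
  expect_true("oc_use" %in% t3w)
})

test_that("zero incident cases raise a no-events error", {
  d <- tibble::tibble(sex = "male", harg = exp(rnorm(50, 0.5, 0.3)),
                      event = 0L)
  expect_error(fit_incident_model(d, "event", stratum = "men"), "no events")
})

test_that("the model grid composes single fits and annotates failed cells", {
  co <- generate_cohort(cohort_params(n_participants = 2500, seed = 47))
  ins_ref <- high_insulin_reference(co)
  base <- suppressMessages(classify_records(co, refs = ins_ref,
                                            cols = c(insulin = "insulin")))
  fu_base <- suppressMessages(classify_records(
    co, refs = ins_ref,
    cols = c(waist = "waist_10y", tg = "tg_10y", hdl = "hdl_10y",
             sbp = "sbp_10y", dbp = "dbp_10y", glucose = "glucose_10y",
             bmi = "bmi_10y", insulin = "insulin_10y", hba1c = "hba1c_10y")))
  grid <- run_model_grid(co, base, fu_base,
                         outcomes = c("obesity", "hyperglycaemia"),
                         tiers = 1:3)
  expect_identical(nrow(grid), 12L)
  expect_true(all(grid$n_incident <= grid$n_at_risk))

  # cell-by-cell agreement with a direct single fit
  rs <- incident_risk_set(base, fu_base, outcomes = "obesity")
  d <- dplyr::inner_join(co, tibble::tibble(id = rs$id, inc = rs$incident), by = "id")
  dm <- dplyr::filter(d, sex == "male")
  single <- fit_incident_model(dm, "inc", tier = 1, stratum = "men")
  cell <- dplyr::filter(grid, outcome == "obesity", stratum == "men", tier == 1)
  expect_equal(cell$or, single$or, tolerance = 1e-12)
  expect_equal(cell$p, single$p, tolerance = 1e-12)

  # a degenerate outcome yields an annotated cell, not an abort
  fu_zero <- fu_base
  fu_zero$obesity[] <- 0L
  grid2 <- run_model_grid(co, base, fu_zero, outcomes = "obesity", tiers = 1)
  expect_true(all(is.na(grid2$or)))
  expect_true(all(grepl("no events", grid2$note)))
})

test_that("incident tidiers report the odds ratio row", {
  d <- binary_exposure_fixture()
  fit <- fit_incident_model(d, "event", exposure = "exposed", tier = 1,
                            stratum = "men", exposure_is_scaled = TRUE)
  td <- tidy(fit)
  expect_equal(td$or, 2.25, tolerance = 1e-6)
  expect_true(glance(fit)$converged)
})
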