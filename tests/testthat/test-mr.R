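test_that("F-statistic is (beta/se)^2 with a weak-instrument flag", {
  expect_equal(f_statistic(0.2, 0.02)$f_statistic, 100)
  expect_false(f_statistic(0.2, 0.02)$weak)
  z <- f_statistic(0, 0.05)
  expect_equal(z$f_statistic, 0)
  expect_true(z$weak)
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("F equals the squared Wald Z reconstructed from the p-value", {
  sim <- generate_two_sample_summary(summary_sim_params(seed = 4))
  ex <- sim$exposure
  f <- f_statistic(ex$beta, ex$se)$f_statistic
  z_from_p <- qnorm(ex$pvalue / 2, lower.tail = FALSE)
  expect_equal(f, z_from_p^2, tolerance = 1e-8)
})

test_that("harmonization keeps, flips or drops each allele orientation correctly", {
  expo <- exposure_3snp()
  # identical labels: kept unchanged
  out_same <- expo
  out_same$beta <- c(0.05, 0.02, -0.01)
  h <- harmonize(expo, out_same)
  expect_true(all(h$action == "kept"))
  expect_equal(h$beta_y, out_same$beta)

  # swapped alleles: sign flipped
  out_sw <- out_same
  out_sw$effect_allele <- expo$other_allele
  out_sw$other_allele <- expo$effect_allele
  h2 <- harmonize(expo, out_sw)
  expect_true(all(h2$action == "flipped"))
  expect_equal(h2$beta_y, -out_same$beta)
  expect_identical(h2$effect_allele, expo$effect_allele)

  # strand-complement labels resolve like the uncomplemented cases
  out_cmp <- out_same
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  out_cmp$effect_allele <- unname(comp[expo$effect_allele])
  out_cmp$other_allele <- unname(comp[expo$other_allele])
  h3 <- harmonize(expo, out_cmp)
  expect_equal(h3$beta_y, out_same$beta)
})

test_that("palindromic variants resolve by frequency or are dropped", {
  expo <- exposure_3snp()
  expo$effect_allele[1] <- "A"; expo$other_allele[1] <- "T"  # palindromic
  out <- expo
  out$beta <- c(0.05, 0.02, -0.01)

  # no frequency information: dropped with reason "ambiguous strand"
  expo_nofreq <- dplyr::select(expo, -eaf)
  out_nofreq <- dplyr::select(out, -eaf)
  h <- suppressMessages(harmonize(expo_nofreq, out_nofreq))
  expect_identical(nrow(h), 2L)
  dropped <- attr(h, "dropped")
  expect_identical(dropped$reason[dropped$rsid == "rs1153858"], "ambiguous strand")

  # informative frequencies on the same side of 0.5: kept
  h2 <- harmonize(expo, out)
  expect_identical(nrow(h2), 3L)

  # frequencies on opposite sides: orientation flipped
  out_fl <- out
  out_fl$eaf[1] <- 0.7
  h3 <- harmonize(expo, out_fl)
  expect_equal(h3$beta_y[h3$rsid == "rs1153858"], -0.05)

  # frequency too close to 0.5: dropped
  out_mid <- out
  out_mid$eaf[1] <- 0.52
  h4 <- suppressMessages(harmonize(expo, out_mid))
  expect_identical(nrow(h4), 2L)
})

test_that("non-overlapping or irreconcilable variants are dropped with reasons", {
  expo <- exposure_3snp()
  out <- expo
  out$beta <- 0.02
  out$rsid[3] <- "rs999"
  h <- suppressMessages(harmonize(expo, out))
  expect_identical(nrow(h), 2L)
  reasons <- attr(h, "dropped")$reason
  expect_true("absent from outcome table" %in% reasons)
  expect_true("absent from exposure table" %in% reasons)

  out2 <- exposure_3snp()
  out2$effect_allele[2] <- "A"; out2$other_allele[2] <- "G"
  h2 <- suppressMessages(harmonize(expo, out2))
  expect_true("allele mismatch" %in% attr(h2, "dropped")$reason)

  out3 <- exposure_3snp()
  out3$rsid <- c("rs1", "rs2", "rs3")
  expect_error(suppressMessages(harmonize(expo, out3)), "no usable instruments")
})

test_that("Wald ratios follow the first-order delta method", {
  w <- wald_ratio(0.25, 0.05, 0.01)
  expect_equal(w$ratio, 0.2)
  expect_equal(w$ratio_se, 0.04)
  # identity instrument
  w1 <- wald_ratio(1, 0.3, 0.07)
  expect_equal(w1$ratio, 0.3)
  expect_equal(w1$ratio_se, 0.07)
  # sign symmetry: negating beta_x negates the ratio, SE unchanged
  wp <- wald_ratio(0.2, 0.1, 0.05)
  wn <- wald_ratio(-0.2, 0.1, 0.05)
  expect_equal(wn$ratio, -wp$ratio)
  expect_equal(wn$ratio_se, wp$ratio_se)
  expect_error(wald_ratio(0, 0.1, 0.05), "null instrument")
})

test_that("IVW reduces to the Wald ratio for a single instrument", {
  h <- tibble::tibble(beta_x = 0.25, se_x = 0.014, beta_y = 0.05, se_y = 0.01)
  iv <- ivw_combine(h)
  expect_equal(iv$estimate, 0.2)
  expect_equal(iv$se_fixed, 0.04)
  expect_equal(iv$se_re, 0.04)
  expect_equal(iv$q, 0)
  expect_identical(iv$df, 0L)
  expect_true(is.na(iv$p_q))
})

test_that("the worked two-instrument example matches the frozen WLS solution", {
  h <- tibble::tibble(beta_x = c(1, 1), se_x = 0.1, beta_y = c(0.1, 0.3),
                      se_y = c(1, 1))
  iv <- ivw_combine(h)
  expect_equal(iv$estimate, 0.2)
  expect_equal(iv$se_fixed, 0.70711, tolerance = 1e-4)
  expect_equal(iv$q, 0.02)
  expect_equal(iv$phi, 1)
  expect_equal(iv$se_re, iv$se_fixed)
  cq <- cochran_q(h)
  expect_equal(cq$q, 0.02)
  expect_identical(cq$df, 1L)
})

test_that("homogeneous ratios give Q = 0 and fixed-width intervals", {
  h <- tibble::tibble(beta_x = c(0.2, 0.4, 0.5), se_x = 0.01,
                      beta_y = 0.3 * c(0.2, 0.4, 0.5), se_y = c(0.02, 0.05, 0.03))
  iv <- ivw_combine(h)
  expect_equal(iv$estimate, 0.3, tolerance = 1e-12)
  expect_equal(iv$q, 0, tolerance = 1e-20)
  expect_equal(iv$phi, 1)
  expect_equal(iv$se_re, iv$se_fixed)
  expect_equal(cochran_q(h)$p_q, 1, tolerance = 1e-10)
})

test_that("IVW agrees with a generic weighted-least-squares oracle to 1e-10", {
  set.seed(10)
  for (rep in 1:100) {
    j <- sample(2:6, 1)
    h <- tibble::tibble(
      beta_x = runif(j, 0.05, 0.5) * sample(c(-1, 1), j, replace = TRUE),
      se_x = runif(j, 0.005, 0.05),
      beta_y = rnorm(j, 0, 0.1),
      se_y = runif(j, 0.01, 0.2)
    )
    iv <- ivw_combine(h)
    fit <- lm(beta_y ~ beta_x - 1, data = h, weights = 1 / h$se_y^2)
    s <- summary(fit)
    expect_equal(iv$estimate, unname(coef(fit)[1]), tolerance = 1e-10)
    # strip the residual dispersion from lm's SE to get the fixed-effects SE
    expect_equal(iv$se_fixed, unname(s$coefficients[1, 2] / s$sigma),
                 tolerance = 1e-10)
    expect_gte(iv$se_re, iv$se_fixed)
  }
})

test_that("rescaling exposure betas rescales the estimate and preserves Q and p", {
  set.seed(12)
  h <- tibble::tibble(beta_x = runif(3, 0.1, 0.4), se_x = 0.01,
                      beta_y = rnorm(3, 0.05, 0.02), se_y = runif(3, 0.02, 0.05))
  a <- ivw_combine(h)
  c_factor <- 3.7
  h2 <- dplyr::mutate(h, beta_x = beta_x * c_factor)
  b <- ivw_combine(h2)
  expect_equal(b$estimate, a$estimate / c_factor, tolerance = 1e-12)
  expect_equal(b$q, a$q, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-10)

  # per-SD exposure betas convert through the scale-factor hook
  d <- ivw_combine(h, scale_factor = 0.65)
  expect_equal(d$estimate, a$estimate * 0.65, tolerance = 1e-12)
})

test_that("Cochran's Q requires at least two instruments", {
  h <- tibble::tibble(beta_x = 0.2, se_x = 0.01, beta_y = 0.05, se_y = 0.02)
  expect_error(cochran_q(h), "at least 2")
})

test_that("the MR grid composes per-outcome calls and annotates failures", {
  expo <- exposure_3snp()
  sim1 <- generate_two_sample_summary(summary_sim_params(true_effect = 0.1, seed = 21))
  sim2 <- generate_two_sample_summary(summary_sim_params(true_effect = 0, seed = 22))
  bad <- exposure_3snp()
  bad$rsid <- c("rsA", "rsB", "rsC")
  grid <- mr_grid(sim1$exposure, list(o1 = sim1$outcome, o2 = sim2$outcome,
                                      broken = bad))
  expect_identical(nrow(grid), 3L)
  single <- ivw_combine(suppressMessages(harmonize(sim1$exposure, sim1$outcome)))
  expect_equal(grid$estimate[grid$outcome == "o1"], single$estimate,
               tolerance = 1e-12)
  expect_true(is.na(grid$estimate[grid$outcome == "broken"]))
  expect_match(grid$note[grid$outcome == "broken"], "no usable instruments")
})

test_that("ivw tidiers and odds-ratio reporting are consistent", {
  h <- tibble::tibble(beta_x = c(0.25, 0.17), se_x = 0.014,
                      beta_y = c(0.02, 0.015), se_y = c(0.01, 0.012))
  iv <- ivw_combine(h, exponentiate = TRUE)
  expect_equal(iv$or, exp(iv$estimate))
  td <- tidy(iv)
  expect_equal(td$or, iv$or)
  gl <- glance(iv)
  expect_identical(gl$j, 2L)
})
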