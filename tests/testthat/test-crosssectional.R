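test_that("zero replacement, log transform and scaling follow the preparation rules", {
  d <- tibble::tibble(met_a = c(0, 2, 4), met_b = c(1, 2, 3))
  prep <- prepare_metabolites(d, metabolites = c("met_a", "met_b"))
  # zeros become half the minimum positive value (1) before logging
  expect_equal(prep$met_a, as.numeric(scale(log(c(1, 2, 4)))))
  for (m in c("met_a", "met_b")) {
    expect_equal(mean(prep[[m]]), 0, tolerance = 1e-10)
    expect_equal(sd(prep[[m]]), 1, tolerance = 1e-10)
  }
  expect_identical(attr(prep, "transform"), "ln-SD-scaled")
})

test_that("per-sex scaling centres and scales within each stratum", {
  set.seed(2)
  d <- tibble::tibble(sex = rep(c("male", "female"), each = 50),
                      met_x = exp(rnorm(100, mean = rep(c(0, 1), each = 50))))
  prep <- prepare_metabolites(d, per_sex = TRUE)
  for (s in c("male", "female")) {
    x <- prep$met_x[prep$sex == s]
    expect_equal(mean(x), 0, tolerance = 1e-10)
    expect_equal(sd(x), 1, tolerance = 1e-10)
  }
})

test_that("degenerate metabolite columns fail loudly and by name", {
  expect_error(prepare_metabolites(tibble::tibble(met_zero = c(0, 0, 0))),
               "met_zero")
  expect_error(prepare_metabolites(tibble::tibble(met_const = c(5, 5, 5))),
               "zero variance")
  expect_error(prepare_metabolites(tibble::tibble(met_neg = c(-1, 2, 3))),
               "negative")
})

test_that("effective-tests count matches the block structure of the panel", {
  # 25 independent blocks of duplicated columns -> k = 25, threshold 0.002
  m25 <- duplicated_block_matrix(blocks = 25, copies = 4)
  eff <- effective_test_threshold(m25)
  expect_identical(eff$k, 25L)
  expect_equal(eff$threshold, 0.002)

  # single column -> k = 1, threshold = alpha
  expect_equal(effective_test_threshold(tibble::tibble(met_a = rnorm(50)))$threshold,
               0.05)

  # 5 distinct columns duplicated 4x -> k = 5, threshold 0.01
  m5 <- duplicated_block_matrix(blocks = 5, copies = 4)
  eff5 <- effective_test_threshold(m5)
  expect_identical(eff5$k, 5L)
  expect_equal(eff5$threshold, 0.01)

  expect_error(effective_test_threshold(m5, variance_target = 1.2), "\\(0, 1\\]")
})

test_that("effective-tests count is invariant to affine rescaling of columns", {
  m <- duplicated_block_matrix(blocks = 6, copies = 3, n = 120, seed = 8)
  scaled <- sweep(m, 2, seq_len(ncol(m)), `*`)
  a <- effective_test_threshold(m)
  b <- effective_test_threshold(scaled)
  expect_identical(a$k, b$k)
})

test_that("scan recovers a metabolite constructed as scaled hArg with beta 1", {
  set.seed(4)
  d <- tibble::tibble(sex = rep("male", 200), harg = exp(rnorm(200, 0.56, 0.34)))
  d$met_self <- as.numeric(scale(log(d$harg)))
  scan <- metabolome_scan(d, metabolites = "met_self", covariates = character())
  row <- scan[scan$stratum == "men", ]
  expect_equal(row$beta, 1, tolerance = 1e-10)
})

test_that("scan recovers a planted association within 3 standard errors", {
  co <- generate_cohort(cohort_params(n_participants = 2000, seed = 21))
  prep <- prepare_metabolites(co, metabolites = c("met_01_1", "met_02_1"),
                              per_sex = TRUE)
  scan <- metabolome_scan(prep, metabolites = c("met_01_1", "met_02_1"))
  planted <- c(met_01_1 = -0.3, met_02_1 = 0.2)
  for (i in seq_len(nrow(scan))) {
    expect_lt(abs(scan$beta[i] - planted[[scan$metabolite[i]]]),
              3 * scan$se[i])
  }
})

test_that("scan type-I error is controlled at the effective-tests threshold", {
  # 400 null metabolites, one stratum: expect ~0.8 rejections at p < 0.002
  set.seed(6)
  n <- 500
  d <- tibble::tibble(sex = rep("male", n), harg = exp(rnorm(n, 0.56, 0.34)))
  null_mets <- setNames(as.data.frame(matrix(exp(rnorm(n * 400, 0, 0.5)), n, 400)),
                        sprintf("met_%03d", 1:400))
  d <- dplyr::bind_cols(d, null_mets)
  prep <- prepare_metabolites(d, metabolites = names(null_mets))
  scan <- metabolome_scan(prep, metabolites = names(null_mets),
                          covariates = character())
  # P(X >= 6 | Binomial(400, 0.002)) < 1e-4
  expect_lte(sum(scan$sig), 5)
})

test_that("scan betas are invariant to affine rescaling of raw metabolite units", {
  co <- generate_cohort(cohort_params(n_participants = 500, seed = 23))
  a <- prepare_metabolites(co, metabolites = "met_01_1", per_sex = TRUE)
  co2 <- dplyr::mutate(co, met_01_1 = met_01_1 * 1000)
  b <- prepare_metabolites(co2, metabolites = "met_01_1", per_sex = TRUE)
  sa <- metabolome_scan(a, metabolites = "met_01_1")
  sb <- metabolome_scan(b, metabolites = "met_01_1")
  expect_equal(sa$beta, sb$beta, tolerance = 1e-10)
})

test_that("rank-deficient scan designs error with the collinear covariates", {
  set.seed(5)
  d <- tibble::tibble(sex = rep("male", 100), harg = exp(rnorm(100)),
                      met_a = exp(rnorm(100)),
                      age = rnorm(100))
  d$age2 <- 2 * d$age
  prep <- prepare_metabolites(d, metabolites = "met_a")
  expect_error(metabolome_scan(prep, metabolites = "met_a",
                               covariates = c("age", "age2")),
               "collinear")
})

test_that("sex-difference Z-statistic matches the normal-CDF oracle", {
  # oracle: Z = 0.3 / sqrt(0.1^2 + 0.1^2) = 2.1213; p = 2 * pnorm(-2.1213)
  res <- sex_difference_z(0.3, 0.1, 0.0, 0.1)
  expect_equal(res$z, 2.1213, tolerance = 1e-4)
  expect_equal(res$p, 0.0339, tolerance = 1e-3)

  eq <- sex_difference_z(0.2, 0.05, 0.2, 0.08)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  # antisymmetry: swapping the sexes flips Z, p unchanged
  fwd <- sex_difference_z(0.4, 0.1, 0.1, 0.2)
  rev <- sex_difference_z(0.1, 0.2, 0.4, 0.1)
  expect_equal(fwd$z, -rev$z)
  expect_equal(fwd$p, rev$p)

  expect_error(sex_difference_z(0.1, 0, 0.2, 0.1), "positive")
})

test_that("scan_sex_differences joins strata per metabolite", {
  co <- generate_cohort(cohort_params(n_participants = 800, seed = 31))
  prep <- prepare_metabolites(co, metabolites = c("met_01_1", "met_03_1"),
                              per_sex = TRUE)
  scan <- metabolome_scan(prep, metabolites = c("met_01_1", "met_03_1"))
  sd_tbl <- scan_sex_differences(scan)
  expect_identical(nrow(sd_tbl), 2L)
  expect_true(all(is.finite(sd_tbl$z)))
})

test_that("BMI-interaction coefficient is invariant to centring BMI", {
  co <- generate_cohort(cohort_params(n_participants = 600, seed = 37))
  prep <- prepare_metabolites(co, metabolites = "met_02_1", per_sex = TRUE)
  a <- bmi_interaction(prep, metabolites = "met_02_1", covariates = "age")
  centred <- dplyr::mutate(prep, bmi = bmi - mean(bmi))
  b <- bmi_interaction(centred, metabolites = "met_02_1", covariates = "age")
  expect_equal(a$interaction_beta, b$interaction_beta, tolerance = 1e-8)
})

test_that("planted BMI interaction is recovered within 3 standard errors", {
  set.seed(41)
  n <- 2000
  d <- tibble::tibble(sex = rep("male", n),
                      harg = exp(rnorm(n, 0.56, 0.34)),
                      bmi = rnorm(n, 25, 4))
  z <- as.numeric(scale(log(d$harg)))
  d$met_i <- 0.1 * z + 0.2 * z * d$bmi + rnorm(n)
  res <- bmi_interaction(d, metabolites = "met_i", covariates = character())
  expect_lt(abs(res$interaction_beta - 0.2), 3 * res$interaction_se)
  expect_lt(res$interaction_p, 1e-6)
})
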