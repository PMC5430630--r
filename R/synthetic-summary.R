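#' Parameters for the two-sample summary-statistics generator
#'
#' Configures [generate_two_sample_summary()], which draws per-SNP GWAS
#' summary rows for an exposure (serum hArg) and an outcome in two
#' non-overlapping samples. For SNP `j` with per-allele exposure effect
#' `beta_x[j]` the generator draws
#' `beta_hat_x[j] ~ N(beta_x[j], se_x[j]^2)` and
#' `beta_hat_y[j] ~ N(theta * beta_x[j] + alpha[j] + eta[j], se_y[j]^2)`,
#' where `eta[j] ~ N(0, heterogeneity_sd^2)` is balanced heterogeneity and
#' `alpha[j]` is a direct (pleiotropic) SNP-outcome effect. Standard errors
#' follow the usual single-variant formula `sd / sqrt(2 p (1-p) n)`, so they
#' shrink as `1/sqrt(n)`.
#'
#' Defaults give instrument F-statistics between roughly 120 and 370 at the
#' exposure GWAS size of 5,143.
#'
#' @param snps Tibble with columns `rsid, effect_allele, other_allele, eaf`
#'   (defaults to the three hArg instruments).
#' @param true_effect Causal effect `theta`, in outcome units per µmol/L hArg.
#' @param exposure_betas Per-allele SNP-exposure effects, µmol/L per effect
#'   allele (length = number of SNPs).
#' @param exposure_n,outcome_n GWAS sample sizes for the two samples.
#' @param exposure_sd,outcome_sd Phenotype SDs used in the SE formula.
#' @param pleiotropy_alphas Direct SNP-outcome effects `alpha[j]` (default 0).
#' @param heterogeneity_sd SD of balanced per-SNP heterogeneity (default 0).
#' @param seed Integer seed.
#'
#' @return A list of class `"summary_sim_params"`.
#' @export
summary_sim_params <- function(snps = default_instrument_snps()[, c("rsid", "effect_allele",
                                                                    "other_allele", "eaf")],
                               true_effect = 0,
                               exposure_betas = c(0.25, 0.17, 0.155),
                               exposure_n = 5143L,
                               outcome_n = 50000L,
                               exposure_sd = 0.65,
                               outcome_sd = 1,
                               pleiotropy_alphas = 0,
                               heterogeneity_sd = 0,
                               seed = 1L) {
  j <- nrow(snps)
  assert_that(j >= 1, "at least one SNP is required")
  assert_that(length(exposure_betas) == j,
              "exposure_betas must have one entry per SNP")
  assert_that(all(snps$eaf > 0 & snps$eaf < 1),
              "effect-allele frequencies must lie strictly inside (0, 1)")
  assert_that(heterogeneity_sd >= 0, "heterogeneity_sd must be non-negative")
  pleiotropy_alphas <- rep_len(pleiotropy_alphas, j)
  structure(
    list(snps = snps, true_effect = true_effect,
         exposure_betas = exposure_betas,
         exposure_n = as.integer(exposure_n), outcome_n = as.integer(outcome_n),
         exposure_sd = exposure_sd, outcome_sd = outcome_sd,
         pleiotropy_alphas = pleiotropy_alphas,
         heterogeneity_sd = heterogeneity_sd,
         seed = as.integer(seed)),
    class = "summary_sim_params"
  )
}

#' Generate two-sample GWAS summary statistics
#'
#' Draws exposure and outcome summary tables in the package's summary-stats
#' dialect (`rsid, effect_allele, other_allele, beta, se, pvalue, n, eaf`).
#' The exposure and outcome draws use independent noise, emulating
#' non-overlapping samples.
#'
#' @param params A [summary_sim_params()] object.
#' @return A list with elements `exposure` and `outcome`, each a tibble.
#' @export
#' @examples
#' sim <- generate_two_sample_summary(summary_sim_params(true_effect = 0.1, seed = 3))
#' sim$exposure
generate_two_sample_summary <- function(params = summary_sim_params()) {
  assert_that(inherits(params, "summary_sim_params"),
              "params must be created by summary_sim_params()")
  set.seed(params$seed)
  snps <- params$snps
  j <- nrow(snps)
  hw <- 2 * snps$eaf * (1 - snps$eaf)

  se_x <- params$exposure_sd / sqrt(hw * params$exposure_n)
  se_y <- params$outcome_sd / sqrt(hw * params$outcome_n)
  assert_that(all(se_x > 0) && all(se_y > 0), "generated SEs must be positive")

  beta_x_hat <- rnorm(j, params$exposure_betas, se_x)
  eta <- if (params$heterogeneity_sd > 0) rnorm(j, 0, params$heterogeneity_sd) else rep(0, j)
  mean_y <- params$true_effect * params$exposure_betas + params$pleiotropy_alphas + eta
  beta_y_hat <- rnorm(j, mean_y, se_y)

  exposure <- tibble::tibble(
    rsid = snps$rsid, effect_allele = snps$effect_allele,
    other_allele = snps$other_allele,
    beta = beta_x_hat, se = se_x, pvalue = two_sided_p(beta_x_hat, se_x),
    n = params$exposure_n, eaf = snps$eaf
  )
  outcome <- tibble::tibble(
    rsid = snps$rsid, effect_allele = snps$effect_allele,
    other_allele = snps$other_allele,
    beta = beta_y_hat, se = se_y, pvalue = two_sided_p(beta_y_hat, se_y),
    n = params$outcome_n, eaf = snps$eaf
  )
  list(exposure = exposure, outcome = outcome)
}
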