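#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()]. All
#' stages run on synthetic data by default; paths to on-disk cohort or
#' summary-statistics files may be supplied instead.
#'
#' @param out_dir Output directory for result tables and the run manifest.
#' @param seed Integer seed governing every random draw in the run.
#' @param n_participants Cohort size for the simulated stages.
#' @param cohort_path Optional TSV of an existing cohort table (otherwise
#'   simulated).
#' @param exposure_path,outcome_paths Optional summary-statistics files for
#'   the MR stage (otherwise simulated under `mr_true_effect`).
#' @param mr_true_effect Causal effect used when simulating MR inputs.
#' @param variance_target,alpha Effective-tests settings for the scan stage.
#' @param tiers Model tiers for the incident-outcome grid.
#' @param scale_factor Optional exposure-SD rescaling for MR (see
#'   [ivw_combine()]).
#' @param stages Which stages to run (subset of `simulate`, `phenotype`,
#'   `scan`, `incident`, `mr`).
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "homarg-results",
                            seed = 1L,
                            n_participants = 2106L,
                            cohort_path = NULL,
                            exposure_path = NULL,
                            outcome_paths = NULL,
                            mr_true_effect = 0,
                            variance_target = 0.95,
                            alpha = 0.05,
                            tiers = 1:3,
                            scale_factor = NULL,
                            stages = c("simulate", "phenotype", "scan", "incident", "mr")) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(cohort_path, exposure_path, unlist(outcome_paths))) {
    assert_that(file.exists(p), sprintf("input path does not exist: %s", p))
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_participants = as.integer(n_participants),
         cohort_path = cohort_path, exposure_path = exposure_path,
         outcome_paths = outcome_paths, mr_true_effect = mr_true_effect,
         variance_target = variance_target, alpha = alpha, tiers = tiers,
         scale_factor = scale_factor, stages = stages),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file; keys match the arguments of
#'   [pipeline_config()].
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — synthetic-data generation,
#' phenotyping, cross-sectional metabolome scan, incident-outcome model grid
#' and two-sample MR — writing versioned TSV outputs, a JSON run manifest
#' (inputs, seed, parameter hash) and a plain-text summary to
#' `config$out_dir`. The run is fully deterministic given the configuration
#' and seed.
#'
#' @param config A [pipeline_config()] object (or path readable by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the result tables and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config object")
  t0 <- Sys.time()
  tables <- list()
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }

  # --- simulate ---------------------------------------------------------
  if (!is.null(config$cohort_path)) {
    cohort <- readr::read_tsv(config$cohort_path, comment = "#", na = "NA",
                              show_col_types = FALSE, progress = FALSE)
    say("loaded cohort: %d rows from %s", nrow(cohort), config$cohort_path)
  } else {
    cohort <- generate_cohort(cohort_params(n_participants = config$n_participants,
                                            seed = config$seed))
    say("simulated cohort: %d participants (seed %d)", nrow(cohort), config$seed)
  }
  if ("simulate" %in% config$stages) tables$cohort <- cohort

  # --- phenotype --------------------------------------------------------
  risk <- NULL
  base_flags <- fu_flags <- NULL
  if (any(c("phenotype", "incident") %in% config$stages)) {
    ins_ref <- high_insulin_reference(cohort, var = "insulin_10y")
    base_flags <- classify_records(
      cohort, refs = ins_ref,
      cols = c(insulin = "insulin")  # baseline insulin against follow-up cuts
    )
    fu_flags <- classify_records(
      cohort, refs = ins_ref,
      cols = c(waist = "waist_10y", tg = "tg_10y", hdl = "hdl_10y",
               sbp = "sbp_10y", dbp = "dbp_10y", glucose = "glucose_10y",
               bmi = "bmi_10y", insulin = "insulin_10y", hba1c = "hba1c_10y",
               agatston = "agatston_7y", imt = "imt_6y", dist = "dist_6y")
    )
    risk <- incident_risk_set(base_flags, fu_flags,
                              outcomes = c("abdominal_obesity", "hypertriglyceridemia",
                                           "low_hdl", "high_bp", "hyperglycaemia",
                                           "obesity", "high_insulin", "t2dm",
                                           "cac_present"))
    say("phenotyping: %d at-risk rows across %d outcomes",
        nrow(risk), length(unique(risk$outcome)))
    tables$baseline_flags <- base_flags
    tables$followup_flags <- fu_flags
    tables$incident_risk <- risk
  }

  # --- scan -------------------------------------------------------------
  if ("scan" %in% config$stages) {
    prepared <- prepare_metabolites(cohort, per_sex = TRUE)
    eff <- effective_test_threshold(prepared,
                                    variance_target = config$variance_target,
                                    alpha = config$alpha)
    say("effective tests: k = %d, per-test threshold %.4g", eff$k, eff$threshold)
    scan <- metabolome_scan(prepared, threshold = eff$threshold)
    sexdiff <- scan_sex_differences(scan)
    say("scan: %d metabolite x stratum rows, %d significant",
        nrow(scan), sum(scan$sig))
    tables$scan <- scan
    tables$scan_sex_differences <- sexdiff
  }

  # --- incident ---------------------------------------------------------
  if ("incident" %in% config$stages) {
    grid <- run_model_grid(cohort, base_flags, fu_flags, tiers = config$tiers)
    say("incident grid: %d cells, %d with estimates",
        nrow(grid), sum(!is.na(grid$or)))
    tables$incident_grid <- grid
  }

  # --- mr ---------------------------------------------------------------
  if ("mr" %in% config$stages) {
    if (!is.null(config$exposure_path)) {
      exposure <- read_summary_stats(config$exposure_path)
      outs <- purrr::map(config$outcome_paths, read_summary_stats)
      if (is.null(names(outs))) {
        names(outs) <- tools::file_path_sans_ext(basename(unlist(config$outcome_paths)))
      }
    } else {
      sim <- generate_two_sample_summary(
        summary_sim_params(true_effect = config$mr_true_effect,
                           seed = config$seed))
      exposure <- sim$exposure
      outs <- list(simulated_outcome = sim$outcome)
    }
    fstats <- dplyr::bind_cols(exposure["rsid"],
                               f_statistic(exposure$beta, exposure$se))
    mr <- mr_grid(exposure, outs, scale_factor = config$scale_factor)
    say("mr: %d outcome(s); F-statistics %s",
        nrow(mr), paste(round(fstats$f_statistic), collapse = "/"))
    tables$instrument_strength <- fstats
    tables$mr <- mr
  }

  # --- outputs ----------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    n_participants = config$n_participants,
    inputs = list(cohort = config$cohort_path, exposure = config$exposure_path,
                  outcomes = config$outcome_paths),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    tables = names(tables)
  )
  # hash of the analytic parameters only (output location excluded)
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  chars <- utf8ToInt(paste(deparse(cfg_for_hash), collapse = ""))
  hash <- sprintf("%08x", sum(chars * seq_along(chars)) %% 4294967291)
  manifest$parameter_hash <- hash

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(tables, config$out_dir, manifest_hash = hash)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(c(sprintf("homarg pipeline run %s (hash %s)", manifest$created, hash),
               log_lines),
             file.path(config$out_dir, "summary.txt"))
  say("wrote %d table(s) to %s", length(tables), config$out_dir)
  invisible(list(tables = tables, manifest = manifest))
}
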