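# File dialects: tab-separated, UTF-8, NA token "NA". Summary-statistics
# files use the header: rsid effect_allele other_allele beta se pvalue n eaf
# (eaf optional).

summary_stats_cols <- c("rsid", "effect_allele", "other_allele",
                        "beta", "se", "pvalue", "n")

#' Read a GWAS summary-statistics table
#'
#' Reads the package's tab-separated summary-statistics dialect and
#' validates it: required columns `rsid, effect_allele, other_allele, beta,
#' se, pvalue, n` (optional `eaf`), unique rsids, strictly positive standard
#' errors. Numeric parsing is locale-independent (`.` decimal separator;
#' scientific notation accepted).
#'
#' @param path Path to a TSV file.
#' @return A tibble in summary-statistics form.
#' @export
read_summary_stats <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  d <- readr::read_tsv(path, comment = "#", na = "NA", show_col_types = FALSE,
                       locale = readr::locale(decimal_mark = "."),
                       progress = FALSE)
  missing <- setdiff(summary_stats_cols, names(d))
  if (length(missing)) {
    abort(sprintf("file '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(d$rsid)) {
    abort(sprintf("file '%s' contains duplicate rsid(s): %s", path,
                  paste(unique(d$rsid[duplicated(d$rsid)]), collapse = ", ")))
  }
  bad <- which(!is.finite(d$se) | d$se <= 0)
  if (length(bad)) {
    abort(sprintf("file '%s': non-positive standard error in row %s", path,
                  paste(bad, collapse = ", ")))
  }
  d
}

#' Write a summary-statistics table
#'
#' @param x Summary-statistics tibble.
#' @param path Output TSV path.
#' @param comment Optional header comment lines (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path, comment = NULL) {
  assert_that(all(summary_stats_cols %in% names(x)),
              "summary-statistics table is missing required columns")
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(x, path, na = "NA", append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path, na = "NA")
  }
  invisible(path)
}

#' Write result tables with a run-manifest header
#'
#' Writes each table as TSV into `dir`, prefixing every file with a comment
#' line carrying the manifest hash so outputs are traceable to the run that
#' produced them.
#'
#' @param tables Named list of tibbles.
#' @param dir Output directory (created if needed).
#' @param manifest_hash Short identifier written in the header comment.
#' @return Character vector of file paths, invisibly.
#' @export
write_results <- function(tables, dir, manifest_hash = "unversioned") {
  assert_that(length(names(tables)) == length(tables) && all(nzchar(names(tables))),
              "tables must be a named list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(tables, function(tb, nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    writeLines(paste0("# manifest: ", manifest_hash), p)
    readr::write_tsv(tibble::as_tibble(tb), p, na = "NA", append = TRUE,
                     col_names = TRUE)
    p
  })
  invisible(unname(paths))
}
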