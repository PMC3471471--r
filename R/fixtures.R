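#' Packaged ACEI cohort baselines
#'
#' Baseline characteristics (size, sex split, age, blood pressure) of eight
#' published heart-failure cohorts treated with ACE inhibitors, transcribed
#' from the cited trials (see the `provenance` column). Post-treatment
#' pressures were not published per group; pair these baselines with
#' synthetic or user-supplied post-treatment pressures for dose-effect
#' fitting.
#'
#' @return A tibble with columns `group`, `size`, `n_male`, `n_female`,
#'   `age_years`, `sbp`, `dbp`, `provenance`.
#' @export
acei_cohort_baselines <- function() {
  readr::read_csv(
    system.file("extdata", "acei_cohort_baselines.csv", package = "windkesselrc"),
    show_col_types = FALSE
  )
}

#' Packaged worked example: enalapril / lisinopril 20 mg/d
#'
#' The reference worked example: baseline, simulated post-treatment and
#' measured post-treatment values for one enalapril and one lisinopril
#' patient at 20 mg/d, including full seven-component hemodynamic profiles
#' and their CII scores for the baseline and simulated scenarios. Measured
#' rows carry only SBP/DBP (the trials did not report the other
#' components).
#'
#' @return A tibble; see `inst/extdata/schema.md` for columns.
#' @seealso [check_reference_example()]
#' @export
acei_reference_profiles <- function() {
  readr::read_csv(
    system.file("extdata", "acei_reference_profiles.csv", package = "windkesselrc"),
    show_col_types = FALSE
  )
}

#' Recompute and check the packaged worked example
#'
#' Recomputes the CII score of every complete profile in
#' [acei_reference_profiles()] from its seven components and compares with
#' the recorded value (tolerance `cii_tol`), and computes the relative
#' error between simulated and measured SBP/DBP for each drug, checking it
#' against the `bp_tol` bound. Report-only: never throws on failure.
#'
#' @param cii_tol Allowed absolute CII discrepancy (default 0.01, the
#'   rounding precision of the recorded scores).
#' @param bp_tol Allowed relative blood-pressure error (default 0.05).
#' @param weights CII weights, see [compute_cii()].
#' @return A list of class `reference_example_check` with elements `cii`
#'   (per-profile tibble), `bp` (per-pressure tibble),
#'   `max_rel_bp_error`, `cii_ok`, `bp_ok`.
#' @examples
#' check_reference_example()
#' @export
check_reference_example <- function(cii_tol = 0.01, bp_tol = 0.05,
                                    weights = cii_weights()) {
  ref <- acei_reference_profiles()
  complete <- ref[!is.na(ref$cii), ]
  cii_tab <- tibble::tibble(
    drug = complete$drug,
    scenario = complete$scenario,
    cii_recorded = complete$cii,
    cii_computed = compute_cii(complete, weights)
  )
  cii_tab$abs_diff <- abs(cii_tab$cii_computed - cii_tab$cii_recorded)
  cii_tab$pass <- cii_tab$abs_diff <= cii_tol

  sim <- ref[ref$scenario == "simulated", ]
  mea <- ref[ref$scenario == "measured", ]
  bp_tab <- purrr::map_dfr(unique(ref$drug), function(dr) {
    s <- sim[sim$drug == dr, ]
    m <- mea[mea$drug == dr, ]
    tibble::tibble(
      drug = dr,
      measure = c("sbp", "dbp"),
      simulated = c(s$sbp, s$dbp),
      measured = c(m$sbp, m$dbp)
    )
  })
  bp_tab$rel_error <- abs(bp_tab$simulated - bp_tab$measured) / bp_tab$measured

  structure(
    list(
      cii = cii_tab,
      bp = bp_tab,
      max_rel_bp_error = max(bp_tab$rel_error),
      cii_ok = all(cii_tab$pass),
      bp_ok = max(bp_tab$rel_error) <= bp_tol
    ),
    class = "reference_example_check"
  )
}

#' @export
print.reference_example_check <- function(x, ...) {
  cat("Reference worked-example check\n")
  cat(sprintf("  CII cells: %s (max |diff| = %.4f)\n",
              if (x$cii_ok) "PASS" else "FAIL", max(x$cii$abs_diff)))
  cat(sprintf("  Simulated-vs-measured BP: %s (max rel error = %.2f%%)\n",
              if (x$bp_ok) "PASS" else "FAIL", 100 * x$max_rel_bp_error))
  invisible(x)
}

#' Read treatment cohort records from a delimited file
#'
#' Validates the cohort schema (`drug`, `dose_mg_d`, `sbp_pre`, `dbp_pre`,
#' `sbp_post`, `dbp_post`, optional `n`) and basic pressure sanity
#' (`sbp > dbp`, `dose >= 0`).
#'
#' @param path CSV file path.
#' @return A tibble of treatment records.
#' @export
read_treatment_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("drug", "dose_mg_d", "sbp_pre", "dbp_pre", "sbp_post", "dbp_post")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols)) {
    abort_input(paste0("Cohort file is missing column(s): ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  if (any(rec$sbp_pre <= rec$dbp_pre) || any(rec$sbp_post <= rec$dbp_post)) {
    abort_input("Every record must satisfy sbp > dbp (pre and post).")
  }
  if (any(rec$dose_mg_d < 0)) abort_input("Doses must be non-negative.")
  rec
}
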