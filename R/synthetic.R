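#' True dose-effect curves used by the synthetic-cohort generator
#'
#' The generating ground truth: enalapril acts predominantly on resistance
#' with a gradual dose response (half-maximal at 12 mg/d); lisinopril acts
#' on resistance and compliance in near-parallel with a sharply rising,
#' early-saturating response (half-maximal at 0.9 mg/d, >95% of the
#' asymptote by 20 mg/d). Effects are fractional: resistance falls, *
#' compliance rises under ACEI vasodilation.
#'
#' @return A tibble with columns `drug`, `quantity`, `E_max`, `d50`.
#' @export
true_dose_curves <- function() {
  tibble::tribble(
    ~drug,        ~quantity,  ~E_max, ~d50,
    "enalapril",  "delta_R",  -0.30,  12,
    "enalapril",  "delta_C",   0.12,  12,
    "lisinopril", "delta_R",  -0.30,  0.9,
    "lisinopril", "delta_C",   0.28,  0.9
  )
}

#' Specification of a synthetic ACEI cohort
#'
#' Study conditions for [generate_synthetic_cohort()]. Baseline (R, C) are
#' drawn uniformly from a heart-failure box (elevated resistance, reduced
#' compliance) chosen so that even the largest simulated treatment effect
#' keeps the post-treatment parameters inside the admissible estimation
#' grid. Blood-pressure measurement noise defaults to 2 mmHg (typical
#' sphygmomanometer repeatability).
#'
#' @param n_patients Number of records.
#' @param R_range,C_range Baseline sampling box (mmHg.s/mL, mL/mmHg).
#' @param truth True curve parameters, as [true_dose_curves()].
#' @param dose_levels Named list of per-drug dose levels (mg/day).
#' @param noise_sd Gaussian noise sd added to all four pressures (mmHg).
#' @param seed RNG seed; a fixed seed makes the cohort byte-identical.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200,
                        R_range = c(2.3, 3.0), C_range = c(0.32, 0.45),
                        truth = true_dose_curves(),
                        dose_levels = list(
                          enalapril = c(2.5, 5, 10, 20, 40),
                          lisinopril = c(1.25, 2.5, 5, 10, 20, 40)
                        ),
                        noise_sd = 2, seed = 1L) {
  if (noise_sd < 0) abort_input("`noise_sd` must be >= 0.")
  if (n_patients < 1) abort_input("`n_patients` must be >= 1.")
  drugs <- unique(truth$drug)
  if (!all(drugs %in% names(dose_levels))) {
    abort_input("`dose_levels` must name every drug in `truth`.")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      R_range = R_range, C_range = C_range,
      truth = tibble::as_tibble(truth), dose_levels = dose_levels,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

true_delta <- function(truth, drug, quantity, dose) {
  row <- truth[truth$drug == drug & truth$quantity == quantity, ]
  emax_curve(row$E_max, row$d50, dose)
}

#' Generate a synthetic ACEI treatment cohort
#'
#' For each record: draw baseline (R, C), compute noiseless pre-treatment
#' SBP/DBP with [forward_bp()], apply the true dose-effect curves to get
#' post-treatment (R, C) and pressures, then add iid Gaussian measurement
#' noise to all four pressures. Records whose noisy pressures leave the
#' range of the mapping surfaces (and would therefore be inestimable) are
#' resampled, with the resample count reported via a message. The true
#' parameters are attached as a ground-truth sidecar for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @param grid Admissible estimation grid (reachability check).
#' @param bp_mode Forward-map mode, see [forward_bp()].
#' @return A tibble of class `synthetic_cohort` in the treatment-record
#'   schema (`patient_id`, `drug`, `dose_mg_d`, `sbp_pre`, `dbp_pre`,
#'   `sbp_post`, `dbp_post`, `n`); the ground truth (true R/C pre and post
#'   and true deltas) is in `attr(, "truth")`.
#' @examples
#' coh <- generate_synthetic_cohort(cohort_spec(n_patients = 4, seed = 7))
#' attr(coh, "truth")
#' @export
generate_synthetic_cohort <- function(spec = cohort_spec(),
                                      grid = parameter_grid(),
                                      bp_mode = "fixed_t") {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  surf_s <- build_surface(grid, "sbp", bp_mode)
  surf_d <- build_surface(grid, "dbp", bp_mode)
  rng_s <- range(surf_s$values)
  rng_d <- range(surf_d$values)

  drugs <- unique(spec$truth$drug)
  n <- spec$n_patients
  drug <- rep_len(drugs, n)
  dose <- vapply(seq_len(n), function(i) {
    lv <- spec$dose_levels[[drug[i]]]
    lv[((i - 1) %/% length(drugs)) %% length(lv) + 1]
  }, numeric(1))

  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  n_resampled <- 0L
  for (i in seq_len(n)) {
    for (attempt in 1:100) {
      R_pre <- stats::runif(1, spec$R_range[1], spec$R_range[2])
      C_pre <- stats::runif(1, spec$C_range[1], spec$C_range[2])
      dR <- true_delta(spec$truth, drug[i], "delta_R", dose[i])
      dC <- true_delta(spec$truth, drug[i], "delta_C", dose[i])
      R_post <- R_pre * (1 + dR)
      C_post <- C_pre * (1 + dC)
      bp <- forward_bp(c(R_pre, R_post), c(C_pre, C_post), mode = bp_mode,
                       grid = grid, warn = FALSE)
      noisy <- c(bp$sbp, bp$dbp) + stats::rnorm(4, sd = spec$noise_sd)
      sbp_pre <- noisy[1]; sbp_post <- noisy[2]
      dbp_pre <- noisy[3]; dbp_post <- noisy[4]
      ok <- sbp_pre > dbp_pre && sbp_post > dbp_post &&
        all(c(sbp_pre, sbp_post) >= rng_s[1]) && all(c(sbp_pre, sbp_post) <= rng_s[2]) &&
        all(c(dbp_pre, dbp_post) >= rng_d[1]) && all(c(dbp_pre, dbp_post) <= rng_d[2])
      if (ok) break
      n_resampled <- n_resampled + 1L
    }
    if (!ok) {
      rlang::abort("Could not sample a reachable record in 100 attempts.",
                   class = c("windkesselrc_error_sampling", "windkesselrc_error"))
    }
    rows[[i]] <- tibble::tibble(
      patient_id = sprintf("P%03d", i), drug = drug[i], dose_mg_d = dose[i],
      sbp_pre = sbp_pre, dbp_pre = dbp_pre,
      sbp_post = sbp_post, dbp_post = dbp_post, n = 1L
    )
    truth_rows[[i]] <- tibble::tibble(
      patient_id = sprintf("P%03d", i),
      R_pre = R_pre, C_pre = C_pre, R_post = R_post, C_post = C_post,
      delta_R = dR, delta_C = dC
    )
  }
  if (n_resampled > 0) {
    rlang::inform(sprintf("Resampled %d unreachable draw(s).", n_resampled))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truth_rows)
  attr(out, "spec") <- spec
  class(out) <- c("synthetic_cohort", class(out))
  out
}
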