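curve_lookup <- function(curves, drug, quantity) {
  if (is.data.frame(curves)) {
    row <- curves[curves$drug == drug & curves$quantity == quantity, ]
    if (nrow(row) != 1) {
      abort_input(sprintf("No fitted %s curve available for drug '%s'.", quantity, drug))
    }
    return(row$curve[[1]])
  }
  if (is.list(curves) && !is.null(curves[[drug]][[quantity]])) {
    return(curves[[drug]][[quantity]])
  }
  abort_input(sprintf("No fitted %s curve available for drug '%s'.", quantity, drug))
}

#' Predict a patient's response to an ACEI dose
#'
#' The end-to-end workflow, one row per patient: estimate the baseline
#' (R, C) from measured SBP/DBP, shift the parameters along the fitted
#' dose-effect curves ([apply_dose()]), run the forward model for the
#' post-treatment pressures, and - when `ef`/`sw` supplements are given -
#' assemble baseline and predicted hemodynamic profiles and their CII
#' scores from the cycle-periodic pressure wave.
#'
#' @param patients Data frame with columns `id`, `sbp`, `dbp` and
#'   optionally `drug`, `dose` (mg/day; missing or 0 means no treatment),
#'   `ef` (%), `sw` (J/beat), `hr` (beats/min override).
#' @param curves Fitted curves: the tibble returned by [fit_dose_curves()]
#'   or a nested list `curves[[drug]][[quantity]]`.
#' @inheritParams estimate_rc
#' @return A tibble of class `prediction_report`: per patient the baseline
#'   estimate (`R`, `C`, `status`, residuals), post-treatment parameters,
#'   predicted `sbp_pred`/`dbp_pred`, and `cii_baseline`/`cii_pred`
#'   (`NA` unless `ef` and `sw` were supplied).
#' @export
predict_patient <- function(patients, curves = NULL, grid = parameter_grid(),
                            bp_mode = c("fixed_t", "extremum"),
                            inertance = 0.23, p_next = 30,
                            waveform = flow_waveform()) {
  bp_mode <- match.arg(bp_mode)
  patients <- tibble::as_tibble(patients)
  need <- c("id", "sbp", "dbp")
  missing_cols <- setdiff(need, names(patients))
  if (length(missing_cols)) {
    abort_input(paste0("`patients` is missing column(s): ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  if (any(patients$sbp <= patients$dbp) || any(patients$dbp <= 0)) {
    abort_input("Every patient must satisfy sbp > dbp > 0.")
  }

  est <- estimate_rc(patients$sbp, patients$dbp, grid, bp_mode,
                     inertance, p_next, waveform)

  rows <- purrr::map(seq_len(nrow(patients)), function(i) {
    pat <- patients[i, ]
    base <- est[i, ]
    out <- tibble::tibble(
      id = pat$id, sbp = pat$sbp, dbp = pat$dbp,
      R = base$R, C = base$C, status = base$status,
      sbp_residual = base$sbp_residual, dbp_residual = base$dbp_residual,
      drug = if ("drug" %in% names(pat)) as.character(pat$drug) else NA_character_,
      dose = if ("dose" %in% names(pat) && !is.na(pat$dose)) pat$dose else 0,
      R_post = NA_real_, C_post = NA_real_,
      sbp_pred = NA_real_, dbp_pred = NA_real_,
      cii_baseline = NA_real_, cii_pred = NA_real_
    )
    if (base$status == "none") return(out)

    if (out$dose > 0) {
      if (is.na(out$drug)) abort_input(sprintf("Patient %s has a dose but no drug.", pat$id))
      cr <- curve_lookup(curves, out$drug, "delta_R")
      cc <- curve_lookup(curves, out$drug, "delta_C")
      post <- apply_dose(base$R, base$C, cr, cc, out$dose, grid = grid)
      out$R_post <- post$R_post
      out$C_post <- post$C_post
    } else {
      out$R_post <- base$R
      out$C_post <- base$C
    }
    bp_post <- forward_bp(out$R_post, out$C_post, inertance, p_next,
                          mode = bp_mode, waveform = waveform,
                          grid = grid, warn = FALSE)
    out$sbp_pred <- bp_post$sbp
    out$dbp_pred <- bp_post$dbp

    has_supp <- all(c("ef", "sw") %in% names(pat)) &&
      !is.na(pat$ef) && !is.na(pat$sw)
    if (has_supp) {
      supp <- list(EF = pat$ef, SW = pat$sw,
                   HR = if ("hr" %in% names(pat) && !is.na(pat$hr)) pat$hr else NULL)
      tt <- seq(0, waveform$timing$cycle_length, length.out = 1601)
      prof_of <- function(R, C) {
        cyc <- assemble_cycle(
          vessel_params(R, C, inertance = inertance, p_next = p_next), waveform
        )
        profile_from_model(
          tibble::tibble(time = tt, pressure = eval_cycle(cyc, tt)),
          waveform = waveform, supplements = supp
        )
      }
      out$cii_baseline <- compute_cii(prof_of(base$R, base$C))
      out$cii_pred <- compute_cii(prof_of(out$R_post, out$C_post))
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("prediction_report", class(tibble::tibble()))
  out
}
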