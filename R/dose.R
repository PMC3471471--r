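#' Relative treatment-induced change of resistance or compliance
#'
#' `delta_r()` returns `(R_post - R_pre) / R_pre`; `delta_c()` the analogue
#' for compliance. These dimensionless fractions are the quantities the
#' dose-effect curves are fitted to; a value of -0.25 means a 25% drop.
#'
#' @param R_pre,R_post,C_pre,C_post Positive pre/post parameter values
#'   (vectors, recycled).
#' @return Numeric fraction(s), always > -1 for positive post values.
#' @examples
#' delta_r(2.0, 1.5)
#' @export
delta_r <- function(R_pre, R_post) {
  if (any(!is.finite(R_pre)) || any(R_pre <= 0)) {
    abort_input("`R_pre` must be positive and finite.")
  }
  (R_post - R_pre) / R_pre
}

#' @rdname delta_r
#' @export
delta_c <- function(C_pre, C_post) {
  if (any(!is.finite(C_pre)) || any(C_pre <= 0)) {
    abort_input("`C_pre` must be positive and finite.")
  }
  (C_post - C_pre) / C_pre
}

#' Estimate per-record (R, C) changes from pre/post blood pressures
#'
#' Runs the inverse estimator on the pre-treatment and post-treatment
#' pressure pairs of each record and derives the relative changes
#' `delta_R`, `delta_C`. Estimator failures (unreachable pressures,
#' non-unique intersections) are propagated as flagged rows, never hidden.
#'
#' @param records A data frame with columns `sbp_pre`, `dbp_pre`,
#'   `sbp_post`, `dbp_post` (mmHg); other columns (e.g. `drug`,
#'   `dose_mg_d`, `n`) are carried through.
#' @inheritParams estimate_rc
#' @return The input tibble with added columns `R_pre`, `C_pre`, `R_post`,
#'   `C_post`, `delta_R`, `delta_C`, `status_pre`, `status_post`.
#' @export
deltas_from_record <- function(records, grid = parameter_grid(),
                               bp_mode = c("fixed_t", "extremum"),
                               inertance = 0.23, p_next = 30,
                               waveform = flow_waveform()) {
  bp_mode <- match.arg(bp_mode)
  records <- tibble::as_tibble(records)
  need <- c("sbp_pre", "dbp_pre", "sbp_post", "dbp_post")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort_input(paste0("`records` is missing column(s): ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  pre <- estimate_rc(records$sbp_pre, records$dbp_pre, grid, bp_mode,
                     inertance, p_next, waveform)
  post <- estimate_rc(records$sbp_post, records$dbp_post, grid, bp_mode,
                      inertance, p_next, waveform)
  records$R_pre <- pre$R
  records$C_pre <- pre$C
  records$R_post <- post$R
  records$C_post <- post$C
  records$status_pre <- pre$status
  records$status_post <- post$status
  ok <- pre$status != "none" & post$status != "none"
  records$delta_R <- ifelse(ok, (post$R - pre$R) / pre$R, NA_real_)
  records$delta_C <- ifelse(ok, (post$C - pre$C) / pre$C, NA_real_)
  records
}

emax_curve <- function(E_max, d50, dose) E_max * dose / (d50 + dose)

#' Fit a saturating dose-effect curve
#'
#' Least-squares fit of the zero-anchored rectangular-hyperbola (Emax) form
#' \deqn{E(d) = E_{max}\, d / (d_{50} + d)}{E(d) = E_max d / (d50 + d)}
#' to per-dose relative changes of resistance or compliance. `E_max` is the
#' asymptotic fractional change, `d50` the dose of half-maximal effect
#' (mg/day). Rows are weighted by group size when an `n` column is present.
#'
#' @param records Data frame with columns `dose` (or `dose_mg_d`), the
#'   response named by `quantity`, and optionally `n` (group sizes) and
#'   `drug`.
#' @param quantity `"delta_R"` or `"delta_C"`.
#' @param drug Optional drug label stored on the fit (defaults to the
#'   records' single `drug` value when present).
#' @return An object of class `dose_effect_curve` with elements `drug`,
#'   `quantity`, `E_max`, `d50`, `fit_rss`, `n_points`, and the underlying
#'   `nls` fit (when non-degenerate). Supports [predict()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' rec <- tibble::tibble(dose = c(5, 10, 20, 40),
#'                       delta_R = -0.30 * dose / (10 + dose))
#' fit_dose_curve(rec, "delta_R")
#' @export
fit_dose_curve <- function(records, quantity = c("delta_R", "delta_C"),
                           drug = NULL) {
  quantity <- match.arg(quantity)
  records <- tibble::as_tibble(records)
  if (!"dose" %in% names(records) && "dose_mg_d" %in% names(records)) {
    records$dose <- records$dose_mg_d
  }
  if (!all(c("dose", quantity) %in% names(records))) {
    abort_input(sprintf("`records` must contain columns `dose` and `%s`.", quantity))
  }
  records <- records[is.finite(records[[quantity]]) & is.finite(records$dose), ]
  if (length(unique(records$dose)) < 3) {
    rlang::abort(
      "At least 3 distinct doses are required to fit a dose-effect curve.",
      class = c("windkesselrc_error_insufficient_data", "windkesselrc_error")
    )
  }
  if (is.null(drug)) {
    drug <- if ("drug" %in% names(records) && length(unique(records$drug)) == 1) {
      as.character(records$drug[1])
    } else {
      NA_character_
    }
  }
  dose <- records$dose
  y <- records[[quantity]]
  w <- if ("n" %in% names(records)) records$n else rep(1, length(y))

  if (all(abs(y) < 1e-12)) {
    out <- structure(
      list(drug = drug, quantity = quantity, E_max = 0,
           d50 = stats::median(dose), fit_rss = 0,
           n_points = length(y), fit = NULL, data = records),
      class = "dose_effect_curve"
    )
    return(out)
  }

  # start values: asymptote from the largest-dose mean, half-effect dose by
  # inverting the hyperbola at the median response
  y_top <- stats::weighted.mean(y[dose == max(dose)], w[dose == max(dose)])
  E0 <- 1.05 * y_top
  if (abs(E0) < 1e-8) E0 <- mean(y)
  d50_0 <- stats::median(dose)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ E_max * dose / (d50 + dose),
      start = list(E_max = E0, d50 = d50_0),
      lower = c(-Inf, 1e-6),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      rlang::abort(
        paste0("Dose-effect fit did not converge: ", conditionMessage(e)),
        class = c("windkesselrc_error_fit", "windkesselrc_error"),
        parent = e
      )
    }
  )
  cf <- stats::coef(fit)
  structure(
    list(
      drug = drug, quantity = quantity,
      E_max = unname(cf[["E_max"]]), d50 = unname(cf[["d50"]]),
      fit_rss = sum(stats::residuals(fit)^2),
      n_points = length(y), fit = fit, data = records
    ),
    class = "dose_effect_curve"
  )
}

#' @export
print.dose_effect_curve <- function(x, ...) {
  cat(sprintf(
    "<dose_effect_curve> %s %s: E_max = %.4g, d50 = %.4g mg/d (rss %.3g, n = %d)\n",
    if (is.na(x$drug)) "(unlabelled)" else x$drug, x$quantity,
    x$E_max, x$d50, x$fit_rss, x$n_points
  ))
  invisible(x)
}

#' Predict the effect fraction at given doses
#'
#' @param object A `dose_effect_curve`.
#' @param dose Doses in mg/day (>= 0).
#' @param ... Unused.
#' @return Predicted fractional changes.
#' @export
predict.dose_effect_curve <- function(object, dose, ...) {
  if (any(dose < 0)) abort_input("`dose` must be non-negative.")
  emax_curve(object$E_max, object$d50, dose)
}

#' Fit dose-effect curves for every drug and both quantities
#'
#' Convenience wrapper over [fit_dose_curve()]: fits `delta_R` and
#' `delta_C` curves per drug and returns one tidy row per fit with the
#' curve object in a list-column.
#'
#' @param records Data frame with columns `drug`, `dose` (or `dose_mg_d`),
#'   `delta_R`, `delta_C`, optionally `n`.
#' @return A tibble with columns `drug`, `quantity`, `E_max`, `d50`,
#'   `fit_rss`, `n_points`, `curve`.
#' @export
fit_dose_curves <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"drug" %in% names(records)) abort_input("`records` must contain a `drug` column.")
  combos <- tidyr::expand_grid(
    drug = unique(records$drug),
    quantity = c("delta_R", "delta_C")
  )
  purrr::pmap_dfr(combos, function(drug, quantity) {
    cur <- fit_dose_curve(records[records$drug == drug, ], quantity, drug = drug)
    tibble::tibble(
      drug = drug, quantity = quantity,
      E_max = cur$E_max, d50 = cur$d50,
      fit_rss = cur$fit_rss, n_points = cur$n_points,
      curve = list(cur)
    )
  })
}

#' Apply a drug dose to baseline (R, C)
#'
#' Scales the baseline parameters by the fitted fractional changes:
#' `R_post = R_base * (1 + curve_R(dose))`, and likewise for compliance.
#' Results falling outside the admissible grid box are clamped to it with a
#' warning; non-positive results are an error.
#'
#' @param R_base,C_base Baseline parameters (positive scalars or vectors).
#' @param curve_R,curve_C `dose_effect_curve` objects for `delta_R` and
#'   `delta_C`.
#' @param dose Dose in mg/day (>= 0), recycled against the baselines.
#' @param grid A [parameter_grid()] giving the clamp box.
#' @return A tibble with columns `R_post`, `C_post`, `clamped`.
#' @export
apply_dose <- function(R_base, C_base, curve_R, curve_C, dose,
                       grid = parameter_grid()) {
  stopifnot(inherits(curve_R, "dose_effect_curve"),
            inherits(curve_C, "dose_effect_curve"))
  if (any(dose < 0)) abort_input("`dose` must be non-negative.")
  if (any(R_base <= 0) || any(C_base <= 0)) {
    abort_input("Baseline `R_base` and `C_base` must be positive.")
  }
  R_post <- R_base * (1 + predict(curve_R, dose))
  C_post <- C_base * (1 + predict(curve_C, dose))
  if (any(R_post <= 0) || any(C_post <= 0)) {
    rlang::abort(
      "Dose effect drives a vascular parameter non-positive.",
      class = c("windkesselrc_error_model", "windkesselrc_error")
    )
  }
  R_cl <- pmin(pmax(R_post, grid$R_min), grid$R_max)
  C_cl <- pmin(pmax(C_post, grid$C_min), grid$C_max)
  clamped <- R_cl != R_post | C_cl != C_post
  if (any(clamped)) {
    rlang::warn(sprintf(
      "%d post-treatment parameter pair(s) clamped to the admissible grid box.",
      sum(clamped)
    ))
  }
  tibble::tibble(R_post = R_cl, C_post = C_cl, clamped = clamped)
}

#' Write / read a fitted dose-effect curve as JSON
#'
#' @param curve A `dose_effect_curve`.
#' @param path File path.
#' @return `write_dose_curve()` returns `path` invisibly;
#'   `read_dose_curve()` returns a `dose_effect_curve` (without the
#'   underlying `nls` object).
#' @export
write_dose_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dose_effect_curve"))
  obj <- list(
    format = "windkesselrc/dose_effect_curve/v1",
    drug = curve$drug, quantity = curve$quantity,
    E_max = curve$E_max, d50 = curve$d50,
    fit_rss = curve$fit_rss, n_points = curve$n_points
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_curve
#' @export
read_dose_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "windkesselrc/dose_effect_curve/v1")) {
    abort_input("Not a windkesselrc dose-effect curve JSON file.")
  }
  structure(
    list(drug = obj$drug, quantity = obj$quantity, E_max = obj$E_max,
         d50 = obj$d50, fit_rss = obj$fit_rss, n_points = obj$n_points,
         fit = NULL, data = NULL),
    class = "dose_effect_curve"
  )
}
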