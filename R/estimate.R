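#' Estimate vascular resistance and compliance from SBP/DBP
#'
#' The fast inverse estimator: builds (or reuses the cached) SBP and DBP
#' mapping surfaces over the admissible grid, extracts the iso-contours of
#' the measured pressures, intersects them
#' ([intersect_contours()]) and Newton-polishes the crossing on the true
#' forward model. Vectorised over `sbp`/`dbp`: one output row per input
#' pair (the primary crossing when several exist).
#'
#' @param sbp,dbp Measured systolic and diastolic pressures in mmHg
#'   (vectors, recycled; requires `sbp > dbp > 0` elementwise).
#' @param grid A [parameter_grid()].
#' @param bp_mode Forward-map mode, see [forward_bp()].
#' @param inertance,p_next,waveform Physics, see [forward_bp()].
#' @param polish Newton-refine the crossings.
#' @return A tibble of class `rc_estimate`, one row per input pair, with
#'   columns `sbp`, `dbp`, `R`, `C`, `sbp_residual`, `dbp_residual`,
#'   `status` (`"unique"`, `"multiple"` or `"none"`), `n_intersections`,
#'   `boundary`. Pressures unreachable on the surfaces give a `"none"` row,
#'   not an error.
#' @examples
#' estimate_rc(150, 90, grid = parameter_grid(n_R = 51, n_C = 51))
#' @export
estimate_rc <- function(sbp, dbp, grid = parameter_grid(),
                        bp_mode = c("fixed_t", "extremum"),
                        inertance = 0.23, p_next = 30,
                        waveform = flow_waveform(), polish = TRUE) {
  bp_mode <- match.arg(bp_mode)
  n <- max(length(sbp), length(dbp))
  sbp <- rep_len(sbp, n)
  dbp <- rep_len(dbp, n)
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) || any(dbp <= 0)) {
    abort_input("`sbp` and `dbp` must be finite with dbp > 0.")
  }
  if (any(sbp <= dbp)) {
    abort_input("Each pair must satisfy sbp > dbp (systolic above diastolic).")
  }

  surf_s <- build_surface(grid, "sbp", bp_mode, inertance, p_next, waveform)
  surf_d <- build_surface(grid, "dbp", bp_mode, inertance, p_next, waveform)

  rows <- purrr::map(seq_len(n), function(i) {
    cs <- tryCatch(extract_isocontour(surf_s, sbp[i]),
                   windkesselrc_error_unreachable = function(e) NULL)
    cd <- tryCatch(extract_isocontour(surf_d, dbp[i]),
                   windkesselrc_error_unreachable = function(e) NULL)
    if (is.null(cs) || is.null(cd)) {
      return(rc_estimate_row(sbp[i], dbp[i], status = "none"))
    }
    est <- intersect_contours(cs, cd, polish = polish)
    est[1, ]
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rc_estimate", class(tibble::tibble()))
  out
}

#' Brute-force (R, C) estimation by dense-grid search
#'
#' Test oracle for [estimate_rc()]: exhaustively minimises
#' `(SBP_model - sbp)^2 + (DBP_model - dbp)^2` over every node of the dense
#' tabulated grid and returns the argmin node (no interpolation, no
#' polishing). Slower and coarser than the contour estimator by
#' construction; the two must agree to within one grid cell.
#'
#' @inheritParams estimate_rc
#' @return A tibble of class `rc_estimate` (one row per pair); `objective`
#'   holds the minimised sum of squares (mmHg^2).
#' @export
brute_force_rc <- function(sbp, dbp, grid = parameter_grid(),
                           bp_mode = c("fixed_t", "extremum"),
                           inertance = 0.23, p_next = 30,
                           waveform = flow_waveform()) {
  bp_mode <- match.arg(bp_mode)
  n <- max(length(sbp), length(dbp))
  sbp <- rep_len(sbp, n)
  dbp <- rep_len(dbp, n)
  if (any(sbp <= dbp)) {
    abort_input("Each pair must satisfy sbp > dbp (systolic above diastolic).")
  }
  surf_s <- build_surface(grid, "sbp", bp_mode, inertance, p_next, waveform)
  surf_d <- build_surface(grid, "dbp", bp_mode, inertance, p_next, waveform)

  rows <- purrr::map(seq_len(n), function(i) {
    obj <- (surf_s$values - sbp[i])^2 + (surf_d$values - dbp[i])^2
    k <- arrayInd(which.min(obj), dim(obj))
    R0 <- surf_s$R[k[1]]
    C0 <- surf_s$C[k[2]]
    out <- rc_estimate_row(
      sbp[i], dbp[i], R = R0, C = C0,
      sbp_residual = surf_s$values[k[1], k[2]] - sbp[i],
      dbp_residual = surf_d$values[k[1], k[2]] - dbp[i],
      status = "unique", n_intersections = 1L,
      boundary = k[1] %in% c(1L, grid$n_R) || k[2] %in% c(1L, grid$n_C)
    )
    out$objective <- min(obj)
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rc_estimate", class(tibble::tibble()))
  out
}
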