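#' Forward map from (R, C) to systolic and diastolic pressure
#'
#' The forward model behind the mapping surfaces. Two modes:
#'
#' * `"fixed_t"` (default): SBP is the closed-form systolic branch with
#'   the reference coefficients `K1 = K2 = 1` sampled at the fixed time
#'   `t = 0.14 s` (scaled with systole duration); DBP is the closed-form
#'   diastolic decay sampled at end-diastole `t = cycle_length`. The
#'   diastolic coefficients follow the sign-repaired convention
#'   `K3 = +200, K4 = +400` (`dbp_policy = "classic"`), which restores the
#'   classic monotone decay toward the boundary pressure and end-diastolic
#'   pressures in the clinical range; `dbp_policy = "literal"` uses the
#'   literal constants `-200, -400` (end-diastolic pressure is then negative
#'   over most of the admissible grid - kept for fidelity checks only).
#' * `"extremum"`: SBP/DBP are the maximum/minimum of the cycle-periodic
#'   assembled closed form ([assemble_cycle()]), sampled densely over one
#'   cycle.
#'
#' The two modes ride different solution conventions and their SBP scales
#' differ substantially (the fixed-t surface spans roughly 107-209 mmHg over
#' the default grid, the periodic-cycle extrema roughly 67-113 mmHg); see the
#' methods vignette.
#'
#' @param R,C Numeric vectors (recycled to common length) of resistance
#'   (mmHg.s/mL) and compliance (mL/mmHg).
#' @param inertance,p_next Fixed physics, see [vessel_params()].
#' @param mode `"fixed_t"` or `"extremum"`.
#' @param dbp_policy Diastolic coefficient policy for `"fixed_t"`:
#'   `"classic"` (sign-repaired, default) or `"literal"` (the reference constants).
#' @param waveform A [flow_waveform()].
#' @param grid Admissible box used only for the out-of-range warning.
#' @param warn Warn when (R, C) falls outside `grid` (values are still
#'   computed).
#' @param n_samples Samples per cycle for the `"extremum"` search.
#' @return A tibble with columns `R`, `C`, `sbp`, `dbp` (mmHg). Errors if
#'   any row yields `sbp <= dbp` (model-inconsistency guard).
#' @examples
#' forward_bp(R = c(2, 2.5), C = 0.45)
#' @export
forward_bp <- function(R, C, inertance = 0.23, p_next = 30,
                       mode = c("fixed_t", "extremum"),
                       dbp_policy = c("classic", "literal"),
                       waveform = flow_waveform(),
                       grid = parameter_grid(), warn = TRUE,
                       n_samples = 1601) {
  mode <- match.arg(mode)
  dbp_policy <- match.arg(dbp_policy)
  if (!is.numeric(R) || !is.numeric(C) || any(R <= 0) || any(C <= 0)) {
    abort_input("`R` and `C` must be positive numeric vectors.")
  }
  n <- max(length(R), length(C))
  R <- rep_len(R, n)
  C <- rep_len(C, n)
  if (warn) {
    out_box <- R < grid$R_min | R > grid$R_max | C < grid$C_min | C > grid$C_max
    if (any(out_box)) {
      rlang::warn(sprintf(
        "%d of %d (R, C) pairs fall outside the admissible grid box; values extrapolate the closed form.",
        sum(out_box), n
      ))
    }
  }

  if (mode == "fixed_t") {
    k_dia <- if (dbp_policy == "classic") c(200, 400) else c(-200, -400)
    bp <- forward_fixed_t(R, C, inertance, p_next, waveform,
                          k_sys = c(1, 1), k_dia = k_dia)
  } else {
    bp <- forward_extremum(R, C, inertance, p_next, waveform, n_samples)
  }

  bad <- which(bp$sbp <= bp$dbp)
  if (length(bad)) {
    rlang::abort(
      sprintf(
        "Model inconsistency: SBP <= DBP at R = %.4g, C = %.4g (coefficient convention failure).",
        R[bad[1]], C[bad[1]]
      ),
      class = c("windkesselrc_error_inconsistent", "windkesselrc_error")
    )
  }
  tibble::tibble(R = R, C = C, sbp = bp$sbp, dbp = bp$dbp)
}

# Vectorised fixed-time forward map. SBP samples the mid-systole branch at
# t_sbp = 0.14 * (Ts / 0.3); DBP samples the free diastolic decay at the end
# of the cycle.
forward_fixed_t <- function(R, C, inertance, p_next, waveform, k_sys, k_dia) {
  tm <- waveform$timing
  t_sbp <- 0.14 * tm$systole_duration / 0.3
  t_dbp <- tm$cycle_length
  rts <- roots_vec(R, C, inertance)
  if (any(rts$disc == 0)) {
    rlang::abort(
      "Repeated characteristic root on the requested (R, C) values.",
      class = c("windkesselrc_error_degenerate_root", "windkesselrc_error")
    )
  }
  br2 <- flow_branches(waveform)[[2]]
  pc2 <- particular_coefs(R, C, inertance, p_next, br2)
  sbp <- Re(k_sys[1] * exp(rts$s1 * t_sbp) + k_sys[2] * exp(rts$s2 * t_sbp)) +
    particular_eval(pc2, t_sbp)
  dbp <- Re(k_dia[1] * exp(rts$s1 * t_dbp) + k_dia[2] * exp(rts$s2 * t_dbp)) + p_next
  list(sbp = sbp, dbp = dbp)
}

forward_extremum <- function(R, C, inertance, p_next, waveform, n_samples) {
  tt <- seq(0, waveform$timing$cycle_length, length.out = n_samples)
  sbp <- numeric(length(R))
  dbp <- numeric(length(R))
  for (i in seq_along(R)) {
    cyc <- assemble_cycle(
      vessel_params(R[i], C[i], inertance = inertance, p_next = p_next),
      waveform
    )
    pr <- eval_cycle(cyc, tt)
    sbp[i] <- max(pr)
    dbp[i] <- min(pr)
  }
  list(sbp = sbp, dbp = dbp)
}
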