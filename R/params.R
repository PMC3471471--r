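#' Cardiac cycle timing
#'
#' Timing of one cardiac cycle. The defaults (0.8 s cycle, 0.3 s systole,
#' i.e. 75 beats/min) are the reference operating point of the vessel model;
#' all closed-form branch boundaries scale with `systole_duration`.
#'
#' @param cycle_length Cycle length in seconds.
#' @param systole_duration Duration of systole in seconds; must lie strictly
#'   inside `(0, cycle_length)`.
#' @return An object of class `cardiac_timing`.
#' @examples
#' cardiac_timing()
#' @export
cardiac_timing <- function(cycle_length = 0.8, systole_duration = 0.3) {
  stop_if_not_number(cycle_length, "cycle_length", positive = TRUE)
  stop_if_not_number(systole_duration, "systole_duration", positive = TRUE)
  if (systole_duration >= cycle_length) {
    abort_input("`systole_duration` must be strictly less than `cycle_length`.")
  }
  structure(
    list(cycle_length = cycle_length, systole_duration = systole_duration),
    class = "cardiac_timing"
  )
}

#' @export
print.cardiac_timing <- function(x, ...) {
  cat(sprintf(
    "<cardiac_timing> cycle %.3g s, systole %.3g s (%.0f beats/min)\n",
    x$cycle_length, x$systole_duration, 60 / x$cycle_length
  ))
  invisible(x)
}

#' Vessel segment parameters
#'
#' Lumped parameters of a single Windkessel vessel segment: resistance `R`
#' (mmHg.s/mL), compliance `C` (mL/mmHg), blood inertance `I`
#' (mmHg.s^2/mL, default 0.23) and the downstream boundary pressure
#' `p_next` (mmHg, default 30). `R` and `C` are the unknowns of the inverse
#' problem; `I` and `p_next` are held fixed.
#'
#' @param R Vascular resistance, mmHg.s/mL (> 0).
#' @param C Vascular compliance, mL/mmHg (> 0).
#' @param inertance Blood inertance, mmHg.s^2/mL (> 0).
#' @param p_next Downstream boundary pressure, mmHg.
#' @return An object of class `vessel_params`.
#' @examples
#' vessel_params(R = 2, C = 0.45)
#' @export
vessel_params <- function(R, C, inertance = 0.23, p_next = 30) {
  stop_if_not_number(R, "R", positive = TRUE)
  stop_if_not_number(C, "C", positive = TRUE)
  stop_if_not_number(inertance, "inertance", positive = TRUE)
  stop_if_not_number(p_next, "p_next")
  structure(
    list(R = R, C = C, inertance = inertance, p_next = p_next),
    class = "vessel_params"
  )
}

#' @export
print.vessel_params <- function(x, ...) {
  disc <- x$R^2 * x$C^2 - 4 * x$C * x$inertance
  kind <- if (disc > 0) "real roots" else if (disc < 0) "complex roots" else "degenerate"
  cat(sprintf(
    "<vessel_params> R = %.4g mmHg.s/mL, C = %.4g mL/mmHg, I = %.3g, P_next = %.3g mmHg (%s)\n",
    x$R, x$C, x$inertance, x$p_next, kind
  ))
  invisible(x)
}

#' Cardiac inflow waveform
#'
#' The periodic inflow driving the vessel segment: a half-sine upstroke and
#' downstroke in early and late systole, a raised full sine in mid-systole,
#' and zero flow in diastole. The amplitude is in model flow units (the
#' reference value 70 is internal to the model and not calibrated to a
#' physiological stroke volume).
#'
#' @param amplitude Peak-scale flow coefficient (model units).
#' @param timing A [cardiac_timing()] object.
#' @return An object of class `flow_waveform`.
#' @seealso [input_flow()]
#' @export
flow_waveform <- function(amplitude = 70, timing = cardiac_timing()) {
  stop_if_not_number(amplitude, "amplitude")
  if (amplitude < 0) abort_input("`amplitude` must be non-negative.")
  stopifnot(inherits(timing, "cardiac_timing"))
  structure(list(amplitude = amplitude, timing = timing), class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "<flow_waveform> amplitude %.3g (model units), systole %.3g s of %.3g s cycle\n",
    x$amplitude, x$timing$systole_duration, x$timing$cycle_length
  ))
  invisible(x)
}

#' Closed-form solution coefficients
#'
#' Coefficients of the homogeneous part of the closed-form pressure solution:
#' `K1`, `K2` for the systolic branch and `K3`, `K4` for the diastolic
#' branch. The defaults are the literal reference constants
#' (`K1 = K2 = 1`, `K3 = -200`, `K4 = -400`); see [forward_bp()] for the
#' repaired diastolic convention used by the default mapping surfaces.
#'
#' @param K1,K2 Systolic homogeneous coefficients.
#' @param K3,K4 Diastolic homogeneous coefficients.
#' @return An object of class `solution_coefficients`.
#' @export
solution_coefficients <- function(K1 = 1, K2 = 1, K3 = -200, K4 = -400) {
  vals <- c(K1 = K1, K2 = K2, K3 = K3, K4 = K4)
  if (!all(is.finite(vals))) abort_input("All coefficients must be finite.")
  structure(as.list(vals), class = "solution_coefficients")
}

#' Admissible (R, C) parameter grid
#'
#' The rectangular box of admissible resistance and compliance values over
#' which the pressure mapping surfaces are tabulated, with its tabulation
#' resolution. Defaults: `R` in \[1.55, 3.60\] mmHg.s/mL, `C` in
#' \[0.30, 0.60\] mL/mmHg, 201 x 201 nodes.
#'
#' @param R_min,R_max Resistance bounds, mmHg.s/mL.
#' @param C_min,C_max Compliance bounds, mL/mmHg.
#' @param n_R,n_C Number of grid nodes in each direction (>= 2).
#' @return An object of class `parameter_grid`.
#' @examples
#' parameter_grid(n_R = 51, n_C = 51)
#' @export
parameter_grid <- function(R_min = 1.55, R_max = 3.60,
                           C_min = 0.30, C_max = 0.60,
                           n_R = 201, n_C = 201) {
  if (!(R_min < R_max) || !(C_min < C_max)) {
    abort_input("Grid bounds must satisfy R_min < R_max and C_min < C_max.")
  }
  if (n_R < 2 || n_C < 2) abort_input("Grid resolutions n_R and n_C must be >= 2.")
  structure(
    list(
      R_min = R_min, R_max = R_max, C_min = C_min, C_max = C_max,
      n_R = as.integer(n_R), n_C = as.integer(n_C)
    ),
    class = "parameter_grid"
  )
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf(
    "<parameter_grid> R in [%.3g, %.3g] (%d nodes), C in [%.3g, %.3g] (%d nodes)\n",
    x$R_min, x$R_max, x$n_R, x$C_min, x$C_max, x$n_C
  ))
  invisible(x)
}

grid_axes <- function(grid) {
  list(
    R = seq(grid$R_min, grid$R_max, length.out = grid$n_R),
    C = seq(grid$C_min, grid$C_max, length.out = grid$n_C)
  )
}
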