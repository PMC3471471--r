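#' Evaluate the cardiac inflow waveform
#'
#' Piecewise-sinusoidal inflow over one cardiac cycle. Writing `Ts` for the
#' systole duration and `A` for the amplitude, the four branches are
#' \deqn{Q(t) = A\,\sin(\pi t / T_s)}{Q(t) = A sin(pi t / Ts)} for
#' `t` in `[0, Ts/4]` and `[3Ts/4, Ts]`,
#' \deqn{Q(t) = A\,\sin(\pi/4) + \tfrac{A}{2}\,\sin\!\big(2\pi (t - T_s/4)/T_s\big)}{
#' Q(t) = A sin(pi/4) + (A/2) sin(2 pi (t - Ts/4)/Ts)} in mid-systole, and 0
#' throughout diastole. The waveform is continuous at all three breakpoints
#' and vanishes at `t = 0` and for all of diastole.
#'
#' @param t Time(s) in seconds, within `[0, cycle_length]`.
#' @param wf A [flow_waveform()].
#' @return Flow in model units, same length as `t`.
#' @examples
#' input_flow(c(0, 0.15, 0.5))
#' @export
input_flow <- function(t, wf = flow_waveform()) {
  stopifnot(inherits(wf, "flow_waveform"))
  tm <- wf$timing
  if (any(!is.finite(t)) || any(t < 0) || any(t > tm$cycle_length)) {
    abort_domain(sprintf(
      "`t` must lie within [0, %.3g] s (one cardiac cycle).", tm$cycle_length
    ))
  }
  Ts <- tm$systole_duration
  A <- wf$amplitude
  out <- numeric(length(t))
  early <- t <= Ts / 4
  mid <- t > Ts / 4 & t <= 3 * Ts / 4
  late <- t > 3 * Ts / 4 & t <= Ts
  out[early] <- A * sin(pi * t[early] / Ts)
  out[mid] <- A * sin(pi / 4) + (A / 2) * sin(2 * pi * (t[mid] - Ts / 4) / Ts)
  out[late] <- A * sin(pi * t[late] / Ts)
  out
}

# Branch descriptions of the inflow as q0 + qs*sin(nu t) + qc*cos(nu t).
# Mid-systole: (A/2) sin(2 pi (t - Ts/4)/Ts) = -(A/2) cos(2 pi t / Ts),
# since the phase shift is exactly a quarter period.
flow_branches <- function(wf) {
  Ts <- wf$timing$systole_duration
  A <- wf$amplitude
  nu1 <- pi / Ts
  nu2 <- 2 * pi / Ts
  list(
    list(q0 = 0, qs = A, qc = 0, nu = nu1, t_lo = 0, t_hi = Ts / 4),
    list(q0 = A * sin(pi / 4), qs = 0, qc = -A / 2, nu = nu2, t_lo = Ts / 4, t_hi = 3 * Ts / 4),
    list(q0 = 0, qs = A, qc = 0, nu = nu1, t_lo = 3 * Ts / 4, t_hi = Ts),
    list(q0 = 0, qs = 0, qc = 0, nu = 1, t_lo = Ts, t_hi = wf$timing$cycle_length)
  )
}
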