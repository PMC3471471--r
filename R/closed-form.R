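#' Characteristic roots of the vessel dynamics
#'
#' Roots of `I C s^2 + R C s + 1 = 0`, the characteristic polynomial of the
#' homogeneous pressure equation. Both roots always have a strictly negative
#' real part (the segment is passive, hence stable). When the discriminant
#' `R^2 C^2 - 4 C I` is negative the roots form a complex-conjugate pair and
#' the free response is a damped oscillation; a vanishing discriminant
#' (repeated root) is rejected with an error because the two-exponential
#' closed form degenerates there.
#'
#' @param p A [vessel_params()] object.
#' @return A length-2 vector `c(s1, s2)` in 1/s; numeric when the roots are
#'   real, complex (conjugate pair, `s1` with positive imaginary part) when
#'   they are not.
#' @examples
#' characteristic_roots(vessel_params(R = 2, C = 0.45))
#' @export
characteristic_roots <- function(p) {
  stopifnot(inherits(p, "vessel_params"))
  disc <- p$R^2 * p$C^2 - 4 * p$C * p$inertance
  if (disc == 0) {
    rlang::abort(
      "Repeated characteristic root (R^2 C^2 = 4 C I): closed form is degenerate here.",
      class = c("windkesselrc_error_degenerate_root", "windkesselrc_error")
    )
  }
  two_ci <- 2 * p$C * p$inertance
  if (disc > 0) {
    rt <- sqrt(disc)
    c(s1 = (-p$R * p$C + rt) / two_ci, s2 = (-p$R * p$C - rt) / two_ci)
  } else {
    alpha <- -p$R / (2 * p$inertance)
    beta <- sqrt(-disc) / two_ci
    c(s1 = complex(real = alpha, imaginary = beta),
      s2 = complex(real = alpha, imaginary = -beta))
  }
}

# Vectorised roots over R, C; always complex storage.
roots_vec <- function(R, C, inertance) {
  disc <- R^2 * C^2 - 4 * C * inertance
  rt <- sqrt(as.complex(disc))
  two_ci <- 2 * C * inertance
  list(s1 = (-R * C + rt) / two_ci, s2 = (-R * C - rt) / two_ci, disc = disc)
}

# Steady (particular) response of I C P'' + R C P' + P = I Q' + R Q + p_next
# to the branch inflow Q = q0 + qs sin(nu t) + qc cos(nu t).
# Vectorised over R, C.
particular_coefs <- function(R, C, inertance, p_next, br) {
  F0 <- R * br$q0 + p_next
  Fs <- R * br$qs - inertance * br$nu * br$qc
  Fc <- R * br$qc + inertance * br$nu * br$qs
  a <- 1 - inertance * C * br$nu^2
  b <- R * C * br$nu
  d <- a^2 + b^2
  list(
    P0 = F0,
    Ps = (a * Fs + b * Fc) / d,
    Pc = (-b * Fs + a * Fc) / d,
    nu = br$nu
  )
}

particular_eval <- function(pc, t) {
  pc$P0 + pc$Ps * sin(pc$nu * t) + pc$Pc * cos(pc$nu * t)
}

particular_deriv <- function(pc, t) {
  pc$nu * (pc$Ps * cos(pc$nu * t) - pc$Pc * sin(pc$nu * t))
}

# Real homogeneous basis (value and derivative) for scalar params.
homog_basis <- function(roots, t) {
  s1 <- roots[["s1"]]
  if (is.complex(s1) && Im(s1) != 0) {
    alpha <- Re(s1); beta <- Im(s1)
    e <- exp(alpha * t); cb <- cos(beta * t); sb <- sin(beta * t)
    list(
      u1 = e * cb, u2 = e * sb,
      d1 = e * (alpha * cb - beta * sb), d2 = e * (alpha * sb + beta * cb)
    )
  } else {
    s1 <- Re(s1); s2 <- Re(roots[["s2"]])
    u1 <- exp(s1 * t); u2 <- exp(s2 * t)
    list(u1 = u1, u2 = u2, d1 = s1 * u1, d2 = s2 * u2)
  }
}

# Re(K_a e^{s1 t} + K_b e^{s2 t}) with real K's; works for both root kinds.
homog_pair_eval <- function(roots, Ka, Kb, t) {
  Re(Ka * exp(as.complex(roots[["s1"]]) * t) +
       Kb * exp(as.complex(roots[["s2"]]) * t))
}

#' Closed-form systolic pressure
#'
#' Pressure on the mid-systole branch (`t` in `[Ts/4, 3Ts/4]`), where the
#' inflow is `A sin(pi/4) + (A/2) sin(2 pi (t - Ts/4)/Ts)`:
#' the real part of `K1 e^{s1 t} + K2 e^{s2 t}` (homogeneous part, with
#' `s1`, `s2` the [characteristic_roots()]) plus the steady sinusoidal
#' response and constant offset (particular part). The default `K1 = K2 = 1`
#' is the reference convention under which the fixed systolic sampling time
#' of [forward_bp()] was defined.
#'
#' @param t Time(s) in seconds within the mid-systole window.
#' @param p A [vessel_params()].
#' @param coeffs A [solution_coefficients()]; only `K1`, `K2` are used.
#' @param waveform A [flow_waveform()].
#' @return Pressure in mmHg, same length as `t`.
#' @examples
#' systolic_pressure(0.14, vessel_params(R = 2, C = 0.45))
#' @export
systolic_pressure <- function(t, p, coeffs = solution_coefficients(),
                              waveform = flow_waveform()) {
  stopifnot(inherits(p, "vessel_params"), inherits(coeffs, "solution_coefficients"))
  Ts <- waveform$timing$systole_duration
  tol <- 1e-9 * Ts
  if (any(t < Ts / 4 - tol) || any(t > 3 * Ts / 4 + tol)) {
    abort_domain(sprintf(
      "`t` must lie within the mid-systole window [%.4g, %.4g] s.", Ts / 4, 3 * Ts / 4
    ))
  }
  roots <- characteristic_roots(p)
  br <- flow_branches(waveform)[[2]]
  pc <- particular_coefs(p$R, p$C, p$inertance, p$p_next, br)
  homog_pair_eval(roots, coeffs$K1, coeffs$K2, t) + particular_eval(pc, t)
}

#' Closed-form diastolic pressure
#'
#' Pressure during diastole (`t` in `[Ts, cycle_length]`), where inflow is
#' zero: `Re(K3 e^{s1 t} + K4 e^{s2 t}) + p_next`, a free decay toward the
#' downstream boundary pressure. With the literal default coefficients
#' (`K3 = -200`, `K4 = -400`) the decay approaches `p_next` from below and
#' end-diastolic pressure is strongly negative over the admissible grid; the
#' sign-repaired convention `K3 = +200, K4 = +400` (used by [forward_bp()])
#' restores the classic monotone decay from above and physiological
#' end-diastolic pressures.
#'
#' @inheritParams systolic_pressure
#' @param coeffs A [solution_coefficients()]; only `K3`, `K4` are used.
#' @param timing A [cardiac_timing()].
#' @return Pressure in mmHg, same length as `t`.
#' @examples
#' diastolic_pressure(0.8, vessel_params(R = 2, C = 0.45),
#'                    coeffs = solution_coefficients(K3 = 200, K4 = 400))
#' @export
diastolic_pressure <- function(t, p, coeffs = solution_coefficients(),
                               timing = cardiac_timing()) {
  stopifnot(inherits(p, "vessel_params"), inherits(coeffs, "solution_coefficients"))
  tol <- 1e-9 * timing$cycle_length
  if (any(t < timing$systole_duration - tol) || any(t > timing$cycle_length + tol)) {
    abort_domain(sprintf(
      "`t` must lie within diastole [%.4g, %.4g] s.",
      timing$systole_duration, timing$cycle_length
    ))
  }
  roots <- characteristic_roots(p)
  homog_pair_eval(roots, coeffs$K3, coeffs$K4, t) + p$p_next
}

#' Assemble the cycle-periodic closed-form pressure wave
#'
#' Solves for the homogeneous coefficients of all four inflow branches so
#' that pressure and its derivative are continuous at the three branch
#' boundaries and periodic across the cycle. The result is the exact
#' steady-state (periodic) solution of the vessel equations under the
#' periodic inflow, assembled analytically; it is what the numeric
#' integrator of [solve_ode_numeric()] converges to.
#'
#' @param p A [vessel_params()].
#' @param waveform A [flow_waveform()].
#' @return An object of class `pressure_cycle`; evaluate it with
#'   [eval_cycle()].
#' @examples
#' cyc <- assemble_cycle(vessel_params(R = 2, C = 0.45))
#' eval_cycle(cyc, c(0, 0.14, 0.8))
#' @export
assemble_cycle <- function(p, waveform = flow_waveform()) {
  stopifnot(inherits(p, "vessel_params"), inherits(waveform, "flow_waveform"))
  tm <- waveform$timing
  Ts <- tm$systole_duration
  Tc <- tm$cycle_length
  roots <- characteristic_roots(p)
  brs <- flow_branches(waveform)
  pcs <- lapply(brs, function(br) particular_coefs(p$R, p$C, p$inertance, p$p_next, br))
  tb <- c(Ts / 4, 3 * Ts / 4, Ts)

  M <- matrix(0, 8, 8)
  rhs <- numeric(8)
  row <- 0L
  for (j in 1:3) {
    hb <- homog_basis(roots, tb[j])
    row <- row + 1L
    M[row, (2 * j - 1):(2 * j)] <- c(hb$u1, hb$u2)
    M[row, (2 * j + 1):(2 * j + 2)] <- -c(hb$u1, hb$u2)
    rhs[row] <- particular_eval(pcs[[j + 1]], tb[j]) - particular_eval(pcs[[j]], tb[j])
    row <- row + 1L
    M[row, (2 * j - 1):(2 * j)] <- c(hb$d1, hb$d2)
    M[row, (2 * j + 1):(2 * j + 2)] <- -c(hb$d1, hb$d2)
    rhs[row] <- particular_deriv(pcs[[j + 1]], tb[j]) - particular_deriv(pcs[[j]], tb[j])
  }
  hb0 <- homog_basis(roots, 0)
  hbT <- homog_basis(roots, Tc)
  row <- row + 1L
  M[row, 7:8] <- c(hbT$u1, hbT$u2)
  M[row, 1:2] <- -c(hb0$u1, hb0$u2)
  rhs[row] <- particular_eval(pcs[[1]], 0) - particular_eval(pcs[[4]], Tc)
  row <- row + 1L
  M[row, 7:8] <- c(hbT$d1, hbT$d2)
  M[row, 1:2] <- -c(hb0$d1, hb0$d2)
  rhs[row] <- particular_deriv(pcs[[1]], 0) - particular_deriv(pcs[[4]], Tc)

  coefs <- solve(M, rhs)
  structure(
    list(
      params = p, waveform = waveform, roots = roots,
      particulars = pcs, coefs = coefs, breakpoints = tb
    ),
    class = "pressure_cycle"
  )
}

#' Evaluate an assembled pressure cycle
#'
#' @param cycle A `pressure_cycle` from [assemble_cycle()].
#' @param t Time(s) in `[0, cycle_length]`.
#' @return Pressure in mmHg.
#' @export
eval_cycle <- function(cycle, t) {
  stopifnot(inherits(cycle, "pressure_cycle"))
  tm <- cycle$waveform$timing
  if (any(t < 0) || any(t > tm$cycle_length)) {
    abort_domain(sprintf("`t` must lie within [0, %.3g] s.", tm$cycle_length))
  }
  k <- findInterval(t, cycle$breakpoints) + 1L
  out <- numeric(length(t))
  for (j in 1:4) {
    sel <- k == j
    if (!any(sel)) next
    hb <- homog_basis(cycle$roots, t[sel])
    out[sel] <- cycle$coefs[2 * j - 1] * hb$u1 + cycle$coefs[2 * j] * hb$u2 +
      particular_eval(cycle$particulars[[j]], t[sel])
  }
  out
}

#' @export
print.pressure_cycle <- function(x, ...) {
  cat(sprintf(
    "<pressure_cycle> R = %.4g, C = %.4g; continuity-matched periodic closed form\n",
    x$params$R, x$params$C
  ))
  invisible(x)
}
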