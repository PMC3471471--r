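# Independent numeric-differentiation oracle for the vessel ODE:
#   I C P'' + R C P' + P - (I Q' + R Q + P_next) = 0
# Derivatives by 5-point central stencils (4th order), so the check is
# independent of the closed-form algebra it verifies.

num_d1 <- function(f, t, h = 1e-3) {
  (-f(t + 2 * h) + 8 * f(t + h) - 8 * f(t - h) + f(t - 2 * h)) / (12 * h)
}

num_d2 <- function(f, t, h = 1e-3) {
  (-f(t + 2 * h) + 16 * f(t + h) - 30 * f(t) + 16 * f(t - h) - f(t - 2 * h)) /
    (12 * h^2)
}

# relative ODE residual of a pressure function on an interval; `flow_fun`
# must accept the same times
ode_residual_rel <- function(p_fun, flow_fun, params, t) {
  R <- params$R
  C <- params$C
  I <- params$inertance
  P <- p_fun(t)
  lhs <- I * C * num_d2(p_fun, t) + R * C * num_d1(p_fun, t) + P
  rhs <- I * num_d1(flow_fun, t) + R * flow_fun(t) + params$p_next
  scale <- pmax(abs(lhs), abs(rhs), 1)
  abs(lhs - rhs) / scale
}

# deterministic lattice of (R, C) values spanning the admissible box,
# avoiding the exact box edges
grid_lattice <- function(n_R = 5, n_C = 4, grid = parameter_grid()) {
  expand.grid(
    R = seq(grid$R_min + 0.01, grid$R_max - 0.01, length.out = n_R),
    C = seq(grid$C_min + 0.005, grid$C_max - 0.005, length.out = n_C)
  )
}

coarse_grid <- function(n = 51) parameter_grid(n_R = n, n_C = n)
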