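wf_default <- flow_waveform()

test_that("systolic closed form satisfies the vessel ODE on the mid-systole branch", {
  lat <- grid_lattice(5, 4)
  tt <- seq(0.08, 0.22, length.out = 50)
  for (k in seq_len(nrow(lat))) {
    p <- vessel_params(lat$R[k], lat$C[k])
    p_fun <- function(t) systolic_pressure(t, p)
    # forcing uses the mid-branch inflow continued smoothly (the stencil
    # never leaves the branch for these interior points)
    q_fun <- function(t) input_flow(t, wf_default)
    res <- ode_residual_rel(p_fun, q_fun, p, tt)
    expect_lt(max(res), 1e-6)
  }
})

test_that("systolic solution with zero homogeneous coefficients still solves the ODE", {
  p <- vessel_params(2.0, 0.45)
  cf <- solution_coefficients(K1 = 0, K2 = 0)
  tt <- seq(0.08, 0.22, length.out = 50)
  res <- ode_residual_rel(
    function(t) systolic_pressure(t, p, coeffs = cf),
    function(t) input_flow(t, wf_default), p, tt
  )
  expect_lt(max(res), 1e-6)
})

test_that("diastolic closed form solves the unforced equation and decays to the boundary", {
  lat <- grid_lattice(5, 4)
  tt <- seq(0.31, 0.79, length.out = 50)
  for (k in seq_len(nrow(lat))) {
    p <- vessel_params(lat$R[k], lat$C[k])
    cf <- solution_coefficients(K3 = 200, K4 = 400)
    res <- ode_residual_rel(
      function(t) diastolic_pressure(t, p, coeffs = cf),
      function(t) rep(0, length(t)), p, tt
    )
    expect_lt(max(res), 1e-6)
  }
  # zero coefficients leave the pure equilibrium at the boundary pressure
  p <- vessel_params(2, 0.45)
  expect_equal(
    diastolic_pressure(seq(0.3, 0.8, by = 0.1), p,
                       coeffs = solution_coefficients(K3 = 0, K4 = 0)),
    rep(30, 6)
  )
})

test_that("closed-form branches reject times outside their windows", {
  p <- vessel_params(2, 0.45)
  expect_error(systolic_pressure(0.05, p), class = "windkesselrc_error_domain")
  expect_error(systolic_pressure(0.25, p), class = "windkesselrc_error_domain")
  expect_error(diastolic_pressure(0.2, p), class = "windkesselrc_error_domain")
  expect_error(diastolic_pressure(0.9, p), class = "windkesselrc_error_domain")
})

test_that("assembled periodic cycle matches the numeric integrator", {
  # one real-root and one complex-root node here; the full lattice sweep is
  # part of the acceptance suite
  for (rc in list(c(2.0, 0.45), c(1.55, 0.30))) {
    p <- vessel_params(rc[1], rc[2])
    tr <- solve_ode_numeric(p)
    cyc <- assemble_cycle(p)
    expect_lt(max(abs(tr$pressure - eval_cycle(cyc, tr$time))), 0.5)
  }
})

test_that("periodic cycle pressure decays monotonically through late diastole", {
  lat <- grid_lattice(4, 3)
  tt <- seq(0.4, 0.8, length.out = 200)
  for (k in seq_len(nrow(lat))) {
    cyc <- assemble_cycle(vessel_params(lat$R[k], lat$C[k]))
    pr <- eval_cycle(cyc, tt)
    expect_true(all(diff(pr) <= 1e-9))
  }
})

test_that("default-coefficient systolic maximum falls strictly inside mid-systole", {
  lat <- grid_lattice(6, 5)
  tt <- seq(0.075, 0.225, length.out = 2001)
  for (k in seq_len(nrow(lat))) {
    p <- vessel_params(lat$R[k], lat$C[k])
    pr <- systolic_pressure(tt, p)
    i <- which.max(pr)
    expect_gt(tt[i], 0.075)
    expect_lt(tt[i], 0.225)
  }
})
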