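zero_profile <- c(MAP = 0, PP = 0, HR = 0, CO = 0, SV = 0, EF = 0, SW = 0)

test_that("the index is a plain weighted sum", {
  expect_identical(compute_cii(zero_profile), 0)
  w <- cii_weights()
  p <- c(MAP = 1, PP = 0, HR = 0, CO = 0, SV = 0, EF = 0, SW = 0)
  expect_equal(compute_cii(p), unname(w["MAP"]))
})

test_that("the index is linear in the profile", {
  p1 <- c(MAP = 110, PP = 50, HR = 72, CO = 5.1, SV = 70, EF = 30, SW = 2.9)
  p2 <- c(MAP = 95, PP = 42, HR = 66, CO = 5.8, SV = 78, EF = 36, SW = 2.4)
  a <- 0.3; b <- 1.7
  expect_equal(
    compute_cii(a * p1 + b * p2),
    a * compute_cii(p1) + b * compute_cii(p2),
    tolerance = 1e-12
  )
})

test_that("component perturbations move the index with the weight signs", {
  base <- c(MAP = 110, PP = 50, HR = 72, CO = 5.1, SV = 70, EF = 30, SW = 2.9)
  cii0 <- compute_cii(base)
  for (comp in c("CO", "SV", "EF")) {
    up <- base; up[comp] <- up[comp] + 1
    expect_lt(compute_cii(up), cii0)
  }
  for (comp in c("MAP", "PP", "SW")) {
    up <- base; up[comp] <- up[comp] + 1
    expect_gt(compute_cii(up), cii0)
  }
})

test_that("missing components are named in the error", {
  bad <- c(MAP = 110, PP = 50, HR = 72, CO = 5.1, SV = 70, EF = 30)
  expect_error(compute_cii(bad), "SW")
  df <- tibble::as_tibble(as.list(zero_profile))
  df$EF <- NULL
  expect_error(score_cii(df), "EF")
})

test_that("score_cii appends one score per profile row", {
  df <- tibble::tibble(
    MAP = c(119, 109), PP = c(54, 51), HR = c(73, 73), CO = c(5.26, 5.48),
    SV = c(72, 75), EF = c(28.35, 32.05), SW = c(2.95, 2.70)
  )
  out <- score_cii(df)
  expect_identical(nrow(out), 2L)
  expect_equal(out$cii, compute_cii(df))
  expect_true(out$cii[2] < out$cii[1])
})

test_that("model-derived profiles expose the documented components", {
  # constant trace with zero flow: pure boundary state
  tr <- tibble::tibble(time = seq(0, 0.8, length.out = 101), pressure = 100)
  prof <- profile_from_model(tr, waveform = flow_waveform(amplitude = 0),
                             supplements = list(EF = 30, SW = 2.9))
  expect_equal(prof$MAP, 100)
  expect_equal(prof$PP, 0)
  expect_equal(prof$SV, 0)
  expect_equal(prof$CO, 0)
  expect_equal(prof$HR, 75)
  expect_error(
    profile_from_model(tr, supplements = list(EF = 30)),
    "SW"
  )
})

test_that("stroke volume equals an independent quadrature of the inflow", {
  wf <- flow_waveform()
  tr0 <- solve_ode_numeric(vessel_params(2, 0.45))
  prof <- profile_from_model(tr0, waveform = wf, supplements = list(EF = 30, SW = 2.9))
  oracle <- stats::integrate(function(t) input_flow(t, wf), 0, 0.075)$value +
    stats::integrate(function(t) input_flow(t, wf), 0.075, 0.225)$value +
    stats::integrate(function(t) input_flow(t, wf), 0.225, 0.3)$value
  expect_equal(prof$SV, oracle, tolerance = 1e-5)
  expect_equal(prof$CO, prof$SV * 75 / 1000, tolerance = 1e-8)
  expect_gt(prof$MAP, 30)
  expect_equal(prof$HR, 75)
  # heart-rate override propagates to CO
  prof73 <- profile_from_model(tr0, waveform = wf,
                               supplements = list(EF = 30, SW = 2.9, HR = 73))
  expect_equal(prof73$HR, 73)
  expect_equal(prof73$CO, prof73$SV * 73 / 1000, tolerance = 1e-8)
})
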