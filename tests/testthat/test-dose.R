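test_that("relative parameter changes follow the defining arithmetic", {
  expect_identical(delta_r(2.0, 2.0), 0)
  expect_equal(delta_r(2.0, 1.5), -0.25)
  expect_equal(delta_r(1.0, 2.0), 1.0)
  expect_equal(delta_c(0.4, 0.5), 0.25)
  expect_error(delta_r(0, 1), class = "windkesselrc_error_input")
  expect_error(delta_c(-0.3, 0.4), class = "windkesselrc_error_input")
})

test_that("sequential relative changes compose multiplicatively", {
  R0 <- 2.4
  d1 <- -0.2
  d2 <- -0.1
  R1 <- R0 * (1 + d1)
  R2 <- R1 * (1 + d2)
  expect_equal(1 + delta_r(R0, R2), (1 + d1) * (1 + d2))
})

test_that("deltas_from_record inverts constructed pre/post records", {
  R_pre <- 2.8; C_pre <- 0.38
  R_post <- R_pre * 0.85; C_post <- C_pre * 1.10
  pre <- forward_bp(R_pre, C_pre)
  post <- forward_bp(R_post, C_post)
  rec <- tibble::tibble(
    drug = "enalapril", dose_mg_d = 10,
    sbp_pre = pre$sbp, dbp_pre = pre$dbp,
    sbp_post = post$sbp, dbp_post = post$dbp
  )
  out <- deltas_from_record(rec)
  expect_identical(out$status_pre, "unique")
  expect_equal(out$delta_R, -0.15, tolerance = 0.02)
  expect_equal(out$delta_C, 0.10, tolerance = 0.02)

  # identical pre/post pressures mean no change
  rec0 <- rec
  rec0$sbp_post <- rec0$sbp_pre
  rec0$dbp_post <- rec0$dbp_pre
  out0 <- deltas_from_record(rec0)
  expect_equal(out0$delta_R, 0, tolerance = 1e-8)
  expect_equal(out0$delta_C, 0, tolerance = 1e-8)
})

test_that("a modest pressure drop from a cohort baseline lowers resistance", {
  rec <- tibble::tibble(sbp_pre = 118, dbp_pre = 78,
                        sbp_post = 110, dbp_post = 74)
  out <- deltas_from_record(rec)
  expect_identical(out$status_pre, "unique")
  expect_identical(out$status_post, "unique")
  expect_true(is.finite(out$delta_R) && is.finite(out$delta_C))
  expect_lt(out$delta_R, 0)
})

test_that("noise-free Emax data are recovered to numerical precision", {
  doses <- c(5, 10, 20, 40)
  rec <- tibble::tibble(dose = doses, delta_R = -0.30 * doses / (10 + doses))
  fit <- fit_dose_curve(rec, "delta_R")
  expect_equal(fit$E_max, -0.30, tolerance = 1e-6)
  expect_equal(fit$d50, 10, tolerance = 1e-6)
  expect_lt(fit$fit_rss, 1e-12)
  expect_equal(predict(fit, 0), 0)
})

test_that("noisy Emax data recover the asymptote within 10%", {
  set.seed(42)
  doses <- rep(c(1.25, 2.5, 5, 10, 20, 40, 60, 80), each = 4)
  truth <- -0.30 * doses / (10 + doses)
  rec <- tibble::tibble(dose = doses, delta_R = truth + rnorm(length(doses), sd = 0.01))
  fit <- fit_dose_curve(rec, "delta_R")
  expect_lt(abs(fit$E_max - (-0.30)) / 0.30, 0.10)
})

test_that("degenerate and under-determined inputs are handled explicitly", {
  flat <- tibble::tibble(dose = c(5, 10, 20), delta_R = c(0, 0, 0))
  fit <- fit_dose_curve(flat, "delta_R")
  expect_equal(fit$E_max, 0)
  expect_equal(predict(fit, 50), 0)
  two <- tibble::tibble(dose = c(5, 10), delta_R = c(-0.1, -0.15))
  expect_error(fit_dose_curve(two, "delta_R"),
               class = "windkesselrc_error_insufficient_data")
})

test_that("group sizes weight the least-squares fit", {
  doses <- c(5, 10, 20, 40, 40)
  y <- -0.30 * doses / (10 + doses)
  y[5] <- y[5] + 0.3 # one heavily corrupted small group
  rec_w <- tibble::tibble(dose = doses, delta_R = y, n = c(100, 100, 100, 100, 1))
  fit_w <- fit_dose_curve(rec_w, "delta_R")
  rec_u <- tibble::tibble(dose = doses, delta_R = y)
  fit_u <- fit_dose_curve(rec_u, "delta_R")
  err_w <- abs(fit_w$E_max + 0.30)
  err_u <- abs(fit_u$E_max + 0.30)
  expect_lt(err_w, err_u)
})

test_that("fitted curves are monotone, saturating and zero-anchored", {
  doses <- c(2.5, 5, 10, 20, 40)
  rec <- tibble::tibble(dose = doses, delta_C = 0.25 * doses / (3 + doses))
  fit <- fit_dose_curve(rec, "delta_C")
  dd <- seq(0, 200, length.out = 400)
  eff <- predict(fit, dd)
  expect_equal(eff[1], 0)
  expect_true(all(diff(eff) >= 0))
  expect_true(all(abs(eff) <= abs(fit$E_max) + 1e-12))
})

test_that("apply_dose scales baselines and clamps to the admissible box", {
  doses <- c(5, 10, 20, 40)
  curve_R <- fit_dose_curve(
    tibble::tibble(dose = doses, delta_R = -0.20 * doses / (10 + doses)), "delta_R"
  )
  curve_C <- fit_dose_curve(
    tibble::tibble(dose = doses, delta_C = 0.15 * doses / (10 + doses)), "delta_C"
  )
  at0 <- apply_dose(2.5, 0.4, curve_R, curve_C, 0)
  expect_equal(at0$R_post, 2.5)
  expect_equal(at0$C_post, 0.4)
  # saturation limit: huge dose approaches (1 + E_max) scaling
  sat <- apply_dose(2.5, 0.4, curve_R, curve_C, 1e9)
  expect_equal(sat$R_post, 2.5 * 0.8, tolerance = 1e-6)
  expect_warning(apply_dose(1.6, 0.4, curve_R, curve_C, 40), "clamped")
  expect_error(apply_dose(-1, 0.4, curve_R, curve_C, 5),
               class = "windkesselrc_error_input")
})

test_that("applied doses round-trip through the estimator within 2%", {
  doses <- c(5, 10, 20, 40)
  curve_R <- fit_dose_curve(
    tibble::tibble(dose = doses, delta_R = -0.25 * doses / (8 + doses)), "delta_R"
  )
  curve_C <- fit_dose_curve(
    tibble::tibble(dose = doses, delta_C = 0.20 * doses / (8 + doses)), "delta_C"
  )
  R0 <- 2.8; C0 <- 0.38; dose <- 15
  post <- apply_dose(R0, C0, curve_R, curve_C, dose)
  pre_bp <- forward_bp(R0, C0)
  post_bp <- forward_bp(post$R_post, post$C_post)
  rec <- tibble::tibble(
    sbp_pre = pre_bp$sbp, dbp_pre = pre_bp$dbp,
    sbp_post = post_bp$sbp, dbp_post = post_bp$dbp
  )
  out <- deltas_from_record(rec)
  expect_equal(out$delta_R, predict(curve_R, dose), tolerance = 0.02)
  expect_equal(out$delta_C, predict(curve_C, dose), tolerance = 0.02)
})

test_that("dose-curve JSON and tidier interfaces are coherent", {
  doses <- c(5, 10, 20, 40)
  fit <- fit_dose_curve(
    tibble::tibble(dose = doses, delta_R = -0.30 * doses / (10 + doses)),
    "delta_R", drug = "enalapril"
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_dose_curve(fit, path)
  back <- read_dose_curve(path)
  expect_equal(back$E_max, fit$E_max)
  expect_equal(back$d50, fit$d50)
  expect_identical(back$drug, "enalapril")
  td <- generics::tidy(fit)
  expect_identical(td$term, c("E_max", "d50"))
  gl <- generics::glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$quantity, "delta_R")
})
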