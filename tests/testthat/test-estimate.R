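test_that("forward-inverse round trip recovers the generating parameters", {
  truth <- forward_bp(2.50, 0.45)
  est <- estimate_rc(truth$sbp, truth$dbp)
  expect_identical(est$status, "unique")
  expect_equal(est$R, 2.50, tolerance = 0.01)
  expect_equal(est$C, 0.45, tolerance = 0.01)
  expect_lt(abs(est$sbp_residual), 0.1)
  expect_lt(abs(est$dbp_residual), 0.1)
})

test_that("the worked 120/70 mmHg example has a unique, tight solution", {
  est <- estimate_rc(120, 70)
  expect_identical(est$status, "unique")
  expect_identical(est$n_intersections, 1L)
  expect_lt(abs(est$sbp_residual), 0.1)
  expect_lt(abs(est$dbp_residual), 0.1)
})

test_that("inverted pressure ordering is rejected", {
  expect_error(estimate_rc(70, 120), class = "windkesselrc_error_input")
  expect_error(estimate_rc(100, 100), class = "windkesselrc_error_input")
})

test_that("unreachable pressures return a flagged result, not an exception", {
  est <- estimate_rc(400, 300)
  expect_identical(est$status, "none")
  expect_true(is.na(est$R))
})

test_that("estimation is deterministic and vectorised", {
  s <- c(130, 150, 170)
  d <- c(75, 90, 100)
  a <- estimate_rc(s, d)
  b <- estimate_rc(s, d)
  expect_identical(a, b)
  expect_identical(nrow(a), 3L)
  one <- estimate_rc(150, 90)
  expect_identical(a$R[2], one$R)
})

test_that("brute-force argmin is a local minimum and near the contour estimate", {
  surf_s <- build_surface(parameter_grid(), "sbp")
  surf_d <- build_surface(parameter_grid(), "dbp")
  for (pair in list(c(150, 90), c(130, 75))) {
    bf <- brute_force_rc(pair[1], pair[2])
    i <- which.min(abs(surf_s$R - bf$R))
    j <- which.min(abs(surf_d$C - bf$C))
    obj <- (surf_s$values - pair[1])^2 + (surf_d$values - pair[2])^2
    neigh <- expand.grid(di = -1:1, dj = -1:1)
    for (k in seq_len(nrow(neigh))) {
      ii <- i + neigh$di[k]; jj <- j + neigh$dj[k]
      if (ii < 1 || jj < 1 || ii > nrow(obj) || jj > ncol(obj)) next
      expect_gte(obj[ii, jj], obj[i, j])
    }
    est <- estimate_rc(pair[1], pair[2])
    cell_R <- diff(surf_s$R)[1]
    cell_C <- diff(surf_d$C)[1]
    expect_lte(abs(est$R - bf$R), cell_R + 1e-12)
    expect_lte(abs(est$C - bf$C), cell_C + 1e-12)
  }
})
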