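test_that("a node-valued target's contour passes by that node", {
  surf <- build_surface(coarse_grid(), "sbp")
  i <- 26L; j <- 26L
  target <- surf$values[i, j]
  ctr <- extract_isocontour(surf, target)
  dmin <- min(sqrt((ctr$R - surf$R[i])^2 + ((ctr$C - surf$C[j]) /
                     diff(range(surf$C)) * diff(range(surf$R)))^2))
  cell <- diff(surf$R)[1]
  expect_lt(dmin, cell)
})

test_that("every contour point re-interpolates to the target level", {
  surf <- build_surface(coarse_grid(), "dbp")
  for (target in c(60, 80, 100)) {
    ctr <- extract_isocontour(surf, target)
    vals <- interp_surface(surf, ctr$R, ctr$C)
    expect_lt(max(abs(vals - target)), 1e-6)
  }
})

test_that("SBP = 120 mmHg yields a single connected contour on the default surface", {
  surf <- build_surface(parameter_grid(), "sbp")
  ctr <- extract_isocontour(surf, 120)
  expect_identical(length(unique(ctr$component)), 1L)
  expect_true(all(ctr$R >= 1.55 & ctr$R <= 3.6))
  expect_true(all(ctr$C >= 0.3 & ctr$C <= 0.6))
})

test_that("unreachable pressures raise the dedicated error", {
  surf <- build_surface(coarse_grid(), "sbp")
  expect_error(extract_isocontour(surf, 5000),
               class = "windkesselrc_error_unreachable")
  expect_error(extract_isocontour(surf, 10),
               class = "windkesselrc_error_unreachable")
})

test_that("synthetic straight contours intersect at the analytic point", {
  line1 <- tibble::tibble(component = 1L, R = c(0, 1), C = c(0, 1))
  line2 <- tibble::tibble(component = 1L, R = c(0, 1), C = c(1, 0))
  hit <- intersect_contours(line1, line2)
  expect_identical(hit$status, "unique")
  expect_equal(hit$R, 0.5, tolerance = 1e-9)
  expect_equal(hit$C, 0.5, tolerance = 1e-9)
})

test_that("parallel contours yield a diagnosed empty intersection", {
  line1 <- tibble::tibble(component = 1L, R = c(0, 1), C = c(0, 0))
  line2 <- tibble::tibble(component = 1L, R = c(0, 1), C = c(1, 1))
  hit <- intersect_contours(line1, line2)
  expect_identical(hit$status, "none")
  expect_identical(hit$n_intersections, 0L)
})

test_that("the 120/70 mmHg level sets cross exactly once inside the grid", {
  surf_s <- build_surface(parameter_grid(), "sbp")
  surf_d <- build_surface(parameter_grid(), "dbp")
  est <- intersect_contours(
    extract_isocontour(surf_s, 120), extract_isocontour(surf_d, 70)
  )
  expect_identical(nrow(est), 1L)
  expect_identical(est$status, "unique")
  expect_true(est$R > 1.55 && est$R < 3.6)
  expect_true(est$C > 0.3 && est$C < 0.6)
  expect_false(est$boundary)
})

test_that("empty contours are rejected", {
  line <- tibble::tibble(component = 1L, R = c(0, 1), C = c(0, 1))
  empty <- line[0, ]
  expect_error(intersect_contours(empty, line), class = "windkesselrc_error_input")
})
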