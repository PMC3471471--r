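test_that("surface nodes equal element-wise forward-model calls", {
  g <- parameter_grid(n_R = 2, n_C = 2)
  surf <- build_surface(g, "sbp", cache = FALSE)
  direct <- forward_bp(
    c(g$R_min, g$R_max, g$R_min, g$R_max),
    c(g$C_min, g$C_min, g$C_max, g$C_max), warn = FALSE
  )
  expect_equal(as.vector(surf$values), direct$sbp)
})

test_that("SBP surface strictly dominates the DBP surface node-wise", {
  s <- build_surface(coarse_grid(), "sbp")
  d <- build_surface(coarse_grid(), "dbp")
  expect_true(all(s$values > d$values))
  expect_true(all(is.finite(s$values)))
  expect_identical(dim(s$values), c(51L, 51L))
})

test_that("bilinear refinement is consistent between resolutions", {
  coarse <- build_surface(parameter_grid(n_R = 51, n_C = 51), "sbp")
  fine <- build_surface(parameter_grid(n_R = 101, n_C = 101), "sbp")
  nodes <- expand.grid(R = fine$R, C = fine$C)
  interp <- interp_surface(coarse, nodes$R, nodes$C)
  expect_lt(max(abs(interp - as.vector(fine$values))), 0.5)
})

test_that("surface cache returns identical values without recomputation", {
  a <- build_surface(coarse_grid(), "dbp")
  t_cached <- system.time(b <- build_surface(coarse_grid(), "dbp"))[["elapsed"]]
  expect_identical(a$values, b$values)
  expect_lt(t_cached, 0.5)
})

test_that("JSON sidecar round-trips a surface losslessly", {
  surf <- build_surface(parameter_grid(n_R = 11, n_C = 9), "sbp")
  path <- withr::local_tempfile(fileext = ".json")
  write_surface(surf, path)
  back <- read_surface(path)
  expect_equal(back$values, surf$values)
  expect_identical(back$kind, "sbp")
  expect_identical(back$bp_mode, surf$bp_mode)
  expect_equal(back$grid$n_R, 11L)
  expect_equal(interp_surface(back, 2.5, 0.45), interp_surface(surf, 2.5, 0.45))
})

test_that("interpolation refuses queries outside the grid box", {
  surf <- build_surface(coarse_grid(), "sbp")
  expect_error(interp_surface(surf, 1.0, 0.45), class = "windkesselrc_error_domain")
})
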