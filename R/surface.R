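the_surface_cache <- new.env(parent = emptyenv())

surface_cache_key <- function(grid, bp_mode, inertance, p_next, waveform) {
  paste(
    format(c(grid$R_min, grid$R_max, grid$C_min, grid$C_max), digits = 17),
    grid$n_R, grid$n_C, bp_mode,
    format(c(inertance, p_next, waveform$amplitude,
             waveform$timing$cycle_length, waveform$timing$systole_duration),
           digits = 17),
    collapse = "|"
  )
}

#' Build a pressure mapping surface over the (R, C) grid
#'
#' Tabulates [forward_bp()] at every grid node, producing the SBP-(R,C) or
#' DBP-(R,C) mapping surface used by the fast estimator. Surfaces are
#' memoised per session (keyed by grid, mode and physics), so repeated
#' estimation calls pay only the contour-extraction cost.
#'
#' @param grid A [parameter_grid()].
#' @param kind `"sbp"` or `"dbp"`.
#' @param bp_mode Forward-map mode passed to [forward_bp()].
#' @param inertance,p_next,waveform Physics, see [forward_bp()].
#' @param cache Reuse/populate the per-session surface cache.
#' @return An object of class `pressure_surface`: the grid axes `R`, `C`,
#'   the `values` matrix (`n_R` x `n_C`, mmHg), and metadata.
#' @examples
#' surf <- build_surface(parameter_grid(n_R = 21, n_C = 21), kind = "sbp")
#' range(surf$values)
#' @export
build_surface <- function(grid = parameter_grid(), kind = c("sbp", "dbp"),
                          bp_mode = c("fixed_t", "extremum"),
                          inertance = 0.23, p_next = 30,
                          waveform = flow_waveform(), cache = TRUE) {
  kind <- match.arg(kind)
  bp_mode <- match.arg(bp_mode)
  stopifnot(inherits(grid, "parameter_grid"))

  key <- surface_cache_key(grid, bp_mode, inertance, p_next, waveform)
  if (cache && !is.null(the_surface_cache[[key]])) {
    pair <- the_surface_cache[[key]]
  } else {
    ax <- grid_axes(grid)
    nodes <- expand.grid(R = ax$R, C = ax$C, KEEP.OUT.ATTRS = FALSE)
    bp <- tryCatch(
      forward_bp(nodes$R, nodes$C, inertance = inertance, p_next = p_next,
                 mode = bp_mode, grid = grid, warn = FALSE),
      error = function(e) {
        rlang::abort(
          paste0("Surface build failed: ", conditionMessage(e)),
          class = c("windkesselrc_error_surface_build", "windkesselrc_error"),
          parent = e
        )
      }
    )
    pair <- list(
      sbp = matrix(bp$sbp, nrow = grid$n_R, ncol = grid$n_C),
      dbp = matrix(bp$dbp, nrow = grid$n_R, ncol = grid$n_C),
      R = ax$R, C = ax$C
    )
    if (cache) the_surface_cache[[key]] <- pair
  }

  structure(
    list(
      grid = grid, kind = kind, bp_mode = bp_mode,
      R = pair$R, C = pair$C, values = pair[[kind]],
      physics = list(inertance = inertance, p_next = p_next, waveform = waveform)
    ),
    class = "pressure_surface"
  )
}

#' @export
print.pressure_surface <- function(x, ...) {
  cat(sprintf(
    "<pressure_surface> %s (%s mode), %d x %d nodes, %.1f-%.1f mmHg\n",
    toupper(x$kind), x$bp_mode, length(x$R), length(x$C),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Bilinear interpolation on a pressure surface
#'
#' @param surface A [build_surface()] result.
#' @param R,C Query coordinates (vectors, recycled); must lie inside the
#'   surface's grid box.
#' @return Interpolated pressures in mmHg.
#' @export
interp_surface <- function(surface, R, C) {
  stopifnot(inherits(surface, "pressure_surface"))
  n <- max(length(R), length(C))
  R <- rep_len(R, n)
  C <- rep_len(C, n)
  Rg <- surface$R
  Cg <- surface$C
  if (any(R < Rg[1]) || any(R > Rg[length(Rg)]) ||
      any(C < Cg[1]) || any(C > Cg[length(Cg)])) {
    abort_domain("Query points must lie inside the surface grid box.")
  }
  i <- pmin(pmax(findInterval(R, Rg), 1L), length(Rg) - 1L)
  j <- pmin(pmax(findInterval(C, Cg), 1L), length(Cg) - 1L)
  fx <- (R - Rg[i]) / (Rg[i + 1L] - Rg[i])
  fy <- (C - Cg[j]) / (Cg[j + 1L] - Cg[j])
  v <- surface$values
  v00 <- v[cbind(i, j)]
  v10 <- v[cbind(i + 1L, j)]
  v01 <- v[cbind(i, j + 1L)]
  v11 <- v[cbind(i + 1L, j + 1L)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Write / read a pressure surface as self-describing JSON
#'
#' The sidecar stores the grid specification, mode, physics and row-major
#' values, so batch estimation can reload a surface instead of rebuilding.
#'
#' @param surface A `pressure_surface`.
#' @param path File path.
#' @return `write_surface()` returns `path` invisibly; `read_surface()`
#'   returns the restored `pressure_surface`.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "pressure_surface"))
  tm <- surface$physics$waveform$timing
  obj <- list(
    format = "windkesselrc/pressure_surface/v1",
    kind = surface$kind,
    bp_mode = surface$bp_mode,
    grid = surface$grid[c("R_min", "R_max", "C_min", "C_max", "n_R", "n_C")],
    physics = list(
      inertance = surface$physics$inertance,
      p_next = surface$physics$p_next,
      amplitude = surface$physics$waveform$amplitude,
      cycle_length = tm$cycle_length,
      systole_duration = tm$systole_duration
    ),
    values_row_major = as.vector(t(surface$values))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "windkesselrc/pressure_surface/v1")) {
    abort_input("Not a windkesselrc pressure-surface JSON file.")
  }
  grid <- do.call(parameter_grid, as.list(obj$grid))
  wf <- flow_waveform(
    amplitude = obj$physics$amplitude,
    timing = cardiac_timing(obj$physics$cycle_length, obj$physics$systole_duration)
  )
  ax <- grid_axes(grid)
  structure(
    list(
      grid = grid, kind = obj$kind, bp_mode = obj$bp_mode,
      R = ax$R, C = ax$C,
      values = matrix(obj$values_row_major, nrow = grid$n_R, ncol = grid$n_C,
                      byrow = TRUE),
      physics = list(inertance = obj$physics$inertance,
                     p_next = obj$physics$p_next, waveform = wf)
    ),
    class = "pressure_surface"
  )
}
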