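#' Extract an iso-contour from a pressure surface
#'
#' Level set of the mapping surface at a measured pressure, extracted by
#' marching squares with linear interpolation along cell edges
#' (via [grDevices::contourLines()]). The points of each connected component
#' are ordered along the curve.
#'
#' @param surface A [build_surface()] result.
#' @param target Pressure level in mmHg; must lie within the surface range.
#' @return A tibble of class `iso_contour` with columns `component`, `R`,
#'   `C`, carrying the target and surface metadata as attributes.
#' @examples
#' surf <- build_surface(parameter_grid(n_R = 41, n_C = 41), kind = "sbp")
#' nrow(extract_isocontour(surf, 150))
#' @export
extract_isocontour <- function(surface, target) {
  stopifnot(inherits(surface, "pressure_surface"))
  stop_if_not_number(target, "target")
  rng <- range(surface$values)
  if (target < rng[1] || target > rng[2]) {
    rlang::abort(
      sprintf(
        "Blood pressure %.4g mmHg unreachable in admissible (R, C) range (surface spans %.4g-%.4g mmHg).",
        target, rng[1], rng[2]
      ),
      class = c("windkesselrc_error_unreachable", "windkesselrc_error")
    )
  }
  cl <- grDevices::contourLines(surface$R, surface$C, surface$values, levels = target)
  if (!length(cl)) {
    rlang::abort(
      sprintf("No level set found at %.4g mmHg.", target),
      class = c("windkesselrc_error_unreachable", "windkesselrc_error")
    )
  }
  out <- purrr::imap(cl, function(comp, idx) {
    tibble::tibble(component = idx, R = comp$x, C = comp$y)
  })
  out <- dplyr::bind_rows(out)
  structure(
    out,
    target = target, kind = surface$kind, bp_mode = surface$bp_mode,
    grid = surface$grid, physics = surface$physics,
    class = c("iso_contour", class(tibble::tibble()))
  )
}

# All crossings between two polyline point sets (grouped by component).
# Returns a two-column matrix (R, C) of intersection points.
polyline_crossings <- function(a, b, tol = 1e-9) {
  seg <- function(df) {
    keep <- df$component[-nrow(df)] == df$component[-1]
    list(
      x1 = df$R[-nrow(df)][keep], y1 = df$C[-nrow(df)][keep],
      x2 = df$R[-1][keep], y2 = df$C[-1][keep]
    )
  }
  sa <- seg(a)
  sb <- seg(b)
  na <- length(sa$x1)
  nb <- length(sb$x1)
  if (!na || !nb) return(matrix(numeric(0), ncol = 2))
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  d1x <- sa$x2[ia] - sa$x1[ia]; d1y <- sa$y2[ia] - sa$y1[ia]
  d2x <- sb$x2[ib] - sb$x1[ib]; d2y <- sb$y2[ib] - sb$y1[ib]
  den <- d1x * d2y - d1y * d2x
  ex <- sb$x1[ib] - sa$x1[ia]; ey <- sb$y1[ib] - sa$y1[ia]
  tt <- (ex * d2y - ey * d2x) / den
  uu <- (ex * d1y - ey * d1x) / den
  hit <- abs(den) > .Machine$double.eps & tt >= -tol & tt <= 1 + tol &
    uu >= -tol & uu <= 1 + tol
  if (!any(hit)) return(matrix(numeric(0), ncol = 2))
  px <- sa$x1[ia][hit] + tt[hit] * d1x[hit]
  py <- sa$y1[ia][hit] + tt[hit] * d1y[hit]
  pts <- matrix(c(px, py), ncol = 2)
  # dedupe crossings that coincide at shared segment endpoints
  scale <- max(diff(range(c(sa$x1, sa$x2))), diff(range(c(sa$y1, sa$y2))), 1e-12)
  keep <- rep(TRUE, nrow(pts))
  if (nrow(pts) > 1) {
    for (k in 2:nrow(pts)) {
      d <- sqrt((pts[seq_len(k - 1), 1] - pts[k, 1])^2 +
                  (pts[seq_len(k - 1), 2] - pts[k, 2])^2)
      if (any(d[keep[seq_len(k - 1)]] < 1e-7 * scale)) keep[k] <- FALSE
    }
  }
  pts[keep, , drop = FALSE]
}

# One or more Newton steps on (forward_bp(R, C) - targets) with a central
# finite-difference Jacobian; refines a contour crossing to the true forward
# model rather than its bilinear tabulation.
polish_rc <- function(R0, C0, sbp, dbp, bp_mode, physics, iters = 3) {
  fwd <- function(R, C) {
    bp <- forward_bp(R, C, inertance = physics$inertance, p_next = physics$p_next,
                     mode = bp_mode, waveform = physics$waveform, warn = FALSE)
    c(bp$sbp, bp$dbp)
  }
  x <- c(R0, C0)
  for (k in seq_len(iters)) {
    f0 <- fwd(x[1], x[2]) - c(sbp, dbp)
    eps <- 1e-6 * pmax(abs(x), 1)
    J <- cbind(
      (fwd(x[1] + eps[1], x[2]) - fwd(x[1] - eps[1], x[2])) / (2 * eps[1]),
      (fwd(x[1], x[2] + eps[2]) - fwd(x[1], x[2] - eps[2])) / (2 * eps[2])
    )
    step <- tryCatch(solve(J, f0), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    x <- x - step
    if (x[1] <= 0 || x[2] <= 0) {
      x <- c(R0, C0)
      break
    }
  }
  x
}

rc_estimate_row <- function(sbp, dbp, R = NA_real_, C = NA_real_,
                            sbp_residual = NA_real_, dbp_residual = NA_real_,
                            status = "none", n_intersections = 0L,
                            boundary = NA) {
  tibble::tibble(
    sbp = sbp, dbp = dbp, R = R, C = C,
    sbp_residual = sbp_residual, dbp_residual = dbp_residual,
    status = status, n_intersections = as.integer(n_intersections),
    boundary = boundary
  )
}

#' Intersect SBP and DBP iso-contours
#'
#' Finds every crossing between the two level-set polylines by exact 2-D
#' segment-pair intersection. When the contours carry forward-model metadata
#' (they do when produced by [extract_isocontour()]), each crossing is
#' refined by Newton root-polishing on the true forward map and residuals
#' are reported; bare geometric contours are intersected as-is.
#'
#' A single crossing yields `status = "unique"`. Several crossings yield
#' `status = "multiple"` with one row per crossing, ordered so that the
#' crossing nearest the dense-grid least-squares argmin comes first (the
#' uniqueness assumption is surfaced, never silently resolved). No crossing
#' yields a single `status = "none"` row of diagnostics.
#'
#' @param c_sbp,c_dbp `iso_contour` objects (or tibbles with `component`,
#'   `R`, `C` columns for bare geometry).
#' @param polish Run Newton refinement when model metadata is available.
#' @return A tibble (class `rc_estimate`) with columns `sbp`, `dbp`, `R`,
#'   `C`, `sbp_residual`, `dbp_residual`, `status`, `n_intersections`,
#'   `boundary`.
#' @export
intersect_contours <- function(c_sbp, c_dbp, polish = TRUE) {
  if (!nrow(c_sbp) || !nrow(c_dbp)) {
    abort_input("Both contours must be non-empty.")
  }
  t_sbp <- attr(c_sbp, "target")
  t_dbp <- attr(c_dbp, "target")
  has_model <- !is.null(attr(c_sbp, "physics")) && !is.null(t_sbp) && !is.null(t_dbp)
  pts <- polyline_crossings(c_sbp, c_dbp)
  n_hit <- nrow(pts)
  tgt_s <- if (is.null(t_sbp)) NA_real_ else t_sbp
  tgt_d <- if (is.null(t_dbp)) NA_real_ else t_dbp

  if (n_hit == 0) {
    out <- rc_estimate_row(tgt_s, tgt_d, status = "none", n_intersections = 0L)
    class(out) <- c("rc_estimate", class(out))
    return(out)
  }

  grid <- attr(c_sbp, "grid")
  physics <- attr(c_sbp, "physics")
  bp_mode <- attr(c_sbp, "bp_mode")

  rows <- vector("list", n_hit)
  for (k in seq_len(n_hit)) {
    R0 <- pts[k, 1]
    C0 <- pts[k, 2]
    if (has_model && polish) {
      rc <- polish_rc(R0, C0, t_sbp, t_dbp, bp_mode, physics)
      R0 <- rc[1]
      C0 <- rc[2]
    }
    if (has_model) {
      bp <- forward_bp(R0, C0, inertance = physics$inertance,
                       p_next = physics$p_next, mode = bp_mode,
                       waveform = physics$waveform, warn = FALSE)
      res_s <- bp$sbp - t_sbp
      res_d <- bp$dbp - t_dbp
    } else {
      res_s <- NA_real_
      res_d <- NA_real_
    }
    on_edge <- if (!is.null(grid)) {
      cell_R <- (grid$R_max - grid$R_min) / (grid$n_R - 1)
      cell_C <- (grid$C_max - grid$C_min) / (grid$n_C - 1)
      (R0 - grid$R_min) < cell_R / 2 || (grid$R_max - R0) < cell_R / 2 ||
        (C0 - grid$C_min) < cell_C / 2 || (grid$C_max - C0) < cell_C / 2
    } else NA
    rows[[k]] <- rc_estimate_row(
      tgt_s, tgt_d, R = R0, C = C0,
      sbp_residual = res_s, dbp_residual = res_d,
      status = if (n_hit == 1) "unique" else "multiple",
      n_intersections = n_hit, boundary = on_edge
    )
  }
  out <- dplyr::bind_rows(rows)

  if (n_hit > 1 && has_model) {
    # order by closeness to the brute-force argmin so the primary row is first
    bf <- brute_force_rc(t_sbp, t_dbp, grid = grid, bp_mode = bp_mode,
                         inertance = physics$inertance, p_next = physics$p_next,
                         waveform = physics$waveform)
    d2 <- (out$R - bf$R)^2 + (out$C - bf$C)^2
    out <- out[order(d2), ]
  }
  class(out) <- c("rc_estimate", class(tibble::tibble()))
  out
}
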