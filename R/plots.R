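#' Plot a pressure mapping surface
#'
#' Filled raster of the surface over the (R, C) grid with overlaid
#' iso-pressure contour lines.
#'
#' @param object A `pressure_surface`.
#' @param bins Approximate number of contour lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pressure_surface <- function(object, bins = 12, ...) {
  df <- tibble::tibble(
    R = rep(object$R, times = length(object$C)),
    C = rep(object$C, each = length(object$R)),
    pressure = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$C, z = .data$pressure)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$pressure)) +
    ggplot2::geom_contour(bins = bins, colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = sprintf("%s (mmHg)", toupper(object$kind))) +
    ggplot2::labs(
      x = "Resistance R (mmHg·s/mL)", y = "Compliance C (mL/mmHg)",
      title = sprintf("%s mapping surface (%s mode)", toupper(object$kind), object$bp_mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a single-cycle pressure trace
#'
#' @param object A `pressure_trace` from [solve_ode_numeric()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pressure_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$pressure)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Time in cycle (s)", y = "Pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' Plot an iso-contour in the (R, C) plane
#'
#' @param object An `iso_contour`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iso_contour <- function(object, ...) {
  tgt <- attr(object, "target")
  kind <- attr(object, "kind")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$R, y = .data$C,
                                       group = .data$component)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::labs(
      x = "Resistance R (mmHg·s/mL)", y = "Compliance C (mL/mmHg)",
      title = sprintf("%s = %.4g mmHg level set", toupper(kind %||% "pressure"), tgt)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-effect curve with its data
#'
#' @param object A `dose_effect_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_effect_curve <- function(object, ...) {
  dmax <- if (!is.null(object$data)) max(object$data$dose) else 4 * object$d50
  dd <- tibble::tibble(dose = seq(0, dmax, length.out = 200))
  dd$effect <- predict(object, dd$dose)
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$dose, y = .data$effect)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "Dose (mg/day)",
      y = sprintf("%s (fraction)", object$quantity),
      title = sprintf("%s dose-effect (E_max = %.3g, d50 = %.3g mg/d)",
                      if (is.na(object$drug)) "" else object$drug,
                      object$E_max, object$d50)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(dose = object$data$dose,
                            effect = object$data[[object$quantity]]),
      colour = "grey30"
    )
  }
  p
}
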