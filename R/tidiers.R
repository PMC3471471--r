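#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted dose-effect curve
#'
#' @param x A `dose_effect_curve`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`E_max`, `d50`): estimate
#'   and, when the underlying least-squares fit is available, standard
#'   error, statistic and p-value.
#' @export
tidy.dose_effect_curve <- function(x, ...) {
  if (!is.null(x$fit)) {
    cf <- summary(x$fit)$coefficients
    tibble::tibble(
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      std.error = cf[, "Std. Error"],
      statistic = cf[, "t value"],
      p.value = cf[, "Pr(>|t|)"]
    )
  } else {
    tibble::tibble(
      term = c("E_max", "d50"),
      estimate = c(x$E_max, x$d50),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    )
  }
}

#' Glance at a fitted dose-effect curve
#'
#' @param x A `dose_effect_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `drug`, `quantity`, `E_max`, `d50`,
#'   `fit_rss`, `sigma`, `n_points`.
#' @export
glance.dose_effect_curve <- function(x, ...) {
  sigma <- if (x$n_points > 2) sqrt(x$fit_rss / (x$n_points - 2)) else NA_real_
  tibble::tibble(
    drug = x$drug, quantity = x$quantity,
    E_max = x$E_max, d50 = x$d50,
    fit_rss = x$fit_rss, sigma = sigma, n_points = x$n_points
  )
}
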