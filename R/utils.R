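abort_input <- function(message, class = "windkesselrc_error_input", ...) {
  rlang::abort(message, class = c(class, "windkesselrc_error"), ...)
}

abort_domain <- function(message, ...) {
  abort_input(message, class = "windkesselrc_error_domain", ...)
}

stop_if_not_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_input(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

# trapezoidal integral over an ordered time grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
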