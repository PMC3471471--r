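cii_components <- c("MAP", "PP", "HR", "CO", "SV", "EF", "SW")

#' Weights of the cardiac integrated index
#'
#' The fixed weighting coefficients of the seven-component cardiac
#' integrated index, in component order MAP, PP, HR, CO, SV, EF, SW. They
#' were derived once by principal component analysis of model outputs and
#' are shipped as constants (the source data for the derivation are not
#' available). Negative weights (CO, SV, EF) reward higher values; positive
#' weights penalise them.
#'
#' @return A named numeric vector of length 7.
#' @examples
#' cii_weights()
#' @export
cii_weights <- function() {
  c(MAP = 0.2333, PP = 0.3084, HR = 0.0415,
    CO = -0.3737, SV = -0.3678, EF = -0.3566, SW = 0.3266)
}

profile_values <- function(profile) {
  if (is.data.frame(profile)) {
    missing_cols <- setdiff(cii_components, names(profile))
    if (length(missing_cols)) {
      abort_input(paste0("Profile is missing component(s): ",
                         paste(missing_cols, collapse = ", "), "."))
    }
    m <- as.matrix(profile[cii_components])
  } else if (is.numeric(profile)) {
    missing_cols <- setdiff(cii_components, names(profile))
    if (length(missing_cols)) {
      abort_input(paste0("Profile is missing component(s): ",
                         paste(missing_cols, collapse = ", "), "."))
    }
    m <- matrix(profile[cii_components], nrow = 1,
                dimnames = list(NULL, cii_components))
  } else {
    abort_input("`profile` must be a named numeric vector or a data frame.")
  }
  if (any(!is.finite(m))) abort_input("All profile components must be finite.")
  m
}

#' Cardiac integrated index (CII)
#'
#' Weighted sum of the seven hemodynamic components
#' \deqn{\mathrm{CII} = \sum_{i=1}^{7} y_i w_i}{CII = sum_i y_i w_i}
#' with the components in their conventional units (MAP, PP in mmHg; HR in
#' beats/min; CO in L/min; SV in mL; EF in %; SW in J/beat) and the fixed
#' weights of [cii_weights()]. The sum is taken over raw (unstandardised)
#' values, so the index is deliberately not invariant to unit changes.
#' Lower CII indicates a better overall cardiac state; a drop under
#' treatment is read as recovery.
#'
#' @param profile A named numeric vector, or a data frame with one row per
#'   profile, containing components `MAP`, `PP`, `HR`, `CO`, `SV`, `EF`,
#'   `SW`.
#' @param weights A named weight vector as from [cii_weights()].
#' @return Numeric CII score(s), one per profile row.
#' @examples
#' compute_cii(c(MAP = 119, PP = 54, HR = 73, CO = 5.26,
#'               SV = 72, EF = 28.35, SW = 2.95))
#' @export
compute_cii <- function(profile, weights = cii_weights()) {
  missing_w <- setdiff(cii_components, names(weights))
  if (length(missing_w)) {
    abort_input(paste0("`weights` is missing component(s): ",
                       paste(missing_w, collapse = ", "), "."))
  }
  m <- profile_values(profile)
  as.numeric(m %*% weights[cii_components])
}

#' Score a table of hemodynamic profiles
#'
#' Tidy wrapper over [compute_cii()]: appends a `cii` column to a data
#' frame of profiles.
#'
#' @param data A data frame with the seven component columns.
#' @param weights See [compute_cii()].
#' @return The input as a tibble with an added `cii` column.
#' @export
score_cii <- function(data, weights = cii_weights()) {
  data <- tibble::as_tibble(data)
  data$cii <- compute_cii(data, weights)
  data
}

#' Derive a hemodynamic profile from the vessel model
#'
#' Assembles the seven-component profile from a single-cycle pressure trace
#' and the inflow waveform. The single-segment model supplies MAP (time
#' average of the trace), PP (trace max minus min), HR (60 / cycle length,
#' overridable), SV (integral of the inflow over the cycle; model flow
#' units, see the vignette for the caveat) and CO (SV x HR / 1000).
#' Ejection fraction and stroke work are ventricular quantities outside a
#' single vessel segment and must be supplied.
#'
#' @param trace A `pressure_trace` (or any data frame with `time` and
#'   `pressure` columns covering one cycle).
#' @param waveform A [flow_waveform()].
#' @param timing A [cardiac_timing()].
#' @param supplements Named list; `EF` (%) and `SW` (J/beat) are mandatory,
#'   `HR` (beats/min) optional.
#' @return A one-row tibble with columns MAP, PP, HR, CO, SV, EF, SW.
#' @export
profile_from_model <- function(trace, waveform = flow_waveform(),
                               timing = waveform$timing,
                               supplements = list()) {
  trace <- tibble::as_tibble(trace)
  if (!all(c("time", "pressure") %in% names(trace))) {
    abort_input("`trace` must have `time` and `pressure` columns.")
  }
  for (comp in c("EF", "SW")) {
    if (is.null(supplements[[comp]])) {
      abort_input(sprintf(
        "Supplement `%s` is mandatory: the single-segment model cannot produce it.", comp
      ))
    }
  }
  tt <- trace$time
  pp <- trace$pressure
  span <- max(tt) - min(tt)
  map <- trapz(tt, pp) / span
  hr <- if (!is.null(supplements$HR)) supplements$HR else 60 / timing$cycle_length
  tq <- seq(0, timing$cycle_length, length.out = 4001)
  sv <- trapz(tq, input_flow(tq, waveform))
  tibble::tibble(
    MAP = map,
    PP = max(pp) - min(pp),
    HR = hr,
    CO = sv * hr / 1000,
    SV = sv,
    EF = supplements$EF,
    SW = supplements$SW
  )
}
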