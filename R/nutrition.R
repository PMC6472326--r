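# Diet to serum-cholesterol pathway: energy-intake shares from solved
# consumption, the fatty-acid / Total:HDL ratio link, and mean shifts of
# the intra-household biomarker strata.

#' Cholesterol response coefficients
#'
#' Change in the Total:HDL serum cholesterol ratio per percentage-point
#' change in the energy-intake share of each fatty-acid class.  Central
#' values default to the established clinical estimates (0.003, -0.026,
#' -0.032 for SFA, MUFA, PUFA); the confidence bounds are synthetic
#' defaults used by the sensitivity machinery and are configurable.
#'
#' @param sfa,mufa,pufa central coefficients.
#' @param lower,upper length-3 bounds (SFA, MUFA, PUFA); must bracket the
#'   central values.
#' @return object of class `cholesterol_coefficients`.
#' @export
cholesterol_coefficients <- function(sfa = 0.003, mufa = -0.026,
                                     pufa = -0.032,
                                     lower = c(sfa - 0.003, mufa - 0.012,
                                               pufa - 0.012),
                                     upper = c(sfa + 0.003, mufa + 0.012,
                                               pufa + 0.012)) {
  central <- c(sfa = sfa, mufa = mufa, pufa = pufa)
  lower <- stats::setNames(lower, names(central))
  upper <- stats::setNames(upper, names(central))
  if (any(lower > central) || any(upper < central)) {
    stop("bounds must bracket the central coefficients", call. = FALSE)
  }
  structure(list(central = central, lower = lower, upper = upper),
            class = "cholesterol_coefficients")
}

#' Energy intake from solved consumption
#'
#' Converts per-commodity real consumption of one household into
#' per-capita/day total energy and fatty-acid energies, and the SFA, MUFA
#' and PUFA energy-intake shares (percent of total energy).
#'
#' @param quantities named vector of real consumption by commodity.
#' @param coeffs a `nutrient_coefficients` object.
#' @param household household label.
#' @param population household person count.
#' @return list with `energy`, `sfa`, `mufa`, `pufa` (kcal/person/day) and
#'   `shares` (percent of total energy, named sfa/mufa/pufa).
#' @export
intake_from_consumption <- function(quantities, coeffs, household,
                                    population) {
  if (any(quantities < -1e-9)) {
    stop("consumption quantities must be non-negative", call. = FALSE)
  }
  ed <- coeffs$energy_density[, household]
  kcal <- pmax(quantities, 0) * ed / (population * 365)
  total <- sum(kcal)
  if (total <= 0) {
    stop("undefined energy-intake shares: total energy is zero",
         call. = FALSE)
  }
  sfa <- sum(kcal * coeffs$sfa[, household])
  mufa <- sum(kcal * coeffs$mufa[, household])
  pufa <- sum(kcal * coeffs$pufa[, household])
  list(energy = total, sfa = sfa, mufa = mufa, pufa = pufa,
       shares = c(sfa = sfa, mufa = mufa, pufa = pufa) / total * 100)
}

#' Change in the Total:HDL cholesterol ratio from fatty-acid share changes
#'
#' Exact linear combination `a_SFA * dSFA + a_MUFA * dMUFA + a_PUFA *
#' dPUFA`, with deltas in percentage points of total dietary energy.
#'
#' @param delta_sfa,delta_mufa,delta_pufa share changes in %-points
#'   (scenario minus same-period baseline).
#' @param coeffs a [cholesterol_coefficients()] object.
#' @param bound `"central"`, `"lower"` or `"upper"` coefficient set.
#' @return change in the Total:HDL ratio (dimensionless).
#' @export
delta_cholesterol <- function(delta_sfa, delta_mufa, delta_pufa,
                              coeffs = cholesterol_coefficients(),
                              bound = "central") {
  a <- coeffs[[bound]]
  a[["sfa"]] * delta_sfa + a[["mufa"]] * delta_mufa + a[["pufa"]] * delta_pufa
}

#' Intra-household biomarker strata
#'
#' Support-point values of the Total:HDL cholesterol ratio with fixed
#' population frequencies.
#'
#' @param support strictly increasing support points.
#' @param frequencies non-negative frequencies summing to one.
#' @return object of class `biomarker_strata`.
#' @export
new_strata <- function(support, frequencies) {
  if (any(diff(support) <= 0)) {
    stop("strata support points must be strictly increasing", call. = FALSE)
  }
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-10) {
    stop("strata frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  structure(list(support = as.numeric(support),
                 frequencies = as.numeric(frequencies)),
            class = "biomarker_strata")
}

#' Shift biomarker strata by a mean change
#'
#' Every support point moves by `delta_c`; frequencies are fixed, so the
#' frequency-weighted mean moves by exactly `delta_c` and the ordering is
#' preserved.
#'
#' @param strata a `biomarker_strata` object.
#' @param delta_c mean change in the Total:HDL ratio.
#' @return shifted `biomarker_strata`.
#' @export
shift_strata <- function(strata, delta_c) {
  strata$support <- strata$support + delta_c
  strata
}

#' @export
print.biomarker_strata <- function(x, ...) {
  cat("<biomarker_strata>", length(x$support), "support points, mean",
      signif(sum(x$support * x$frequencies), 4), "\n")
  invisible(x)
}
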