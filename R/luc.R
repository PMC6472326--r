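# Land allocation across primary crops and direct land-use-change GHG
# emissions from an antisymmetric crop-to-crop coefficient matrix.

#' Crop land allocation from a solved equilibrium
#'
#' Hectares per crop follow the land factor employed by each crop activity
#' (converted at the fixed hectares-per-land-unit benchmark ratio); land-
#' yield coefficients (hectares per unit real output) are reported
#' alongside.  At the benchmark this reproduces the calibration areas and
#' `hectares = real output x land coefficient` exactly.
#'
#' @param land_use named vector of land factor employment by crop activity.
#' @param crop_output named vector of real crop outputs.
#' @param hectares0 benchmark hectares by crop (sets the conversion and the
#'   total endowment).
#' @return object of class `land_account` with `hectares` and `yields`.
#' @export
land_allocation <- function(land_use, crop_output, hectares0) {
  if (any(crop_output < 0)) stop("crop outputs must be non-negative",
                                 call. = FALSE)
  conv <- sum(hectares0) / sum(land_use)
  ha <- land_use * conv
  total <- sum(hectares0)
  if (sum(ha) > total * (1 + 1e-8)) {
    stop("allocated land exceeds the endowment", call. = FALSE)
  }
  structure(list(hectares = ha,
                 yields = ifelse(crop_output > 0, ha / crop_output, 0),
                 total = total),
            class = "land_account")
}

#' Direct land-use-change GHG emissions between two land accounts
#'
#' Net area losses are matched to net area gains by proportional
#' allocation; the emission flow is `sum(transition_ij * m_ij)` with `m`
#' in tonnes CO2-eq per hectare converted (antisymmetric, zero diagonal),
#' reported in Mt CO2-eq.
#'
#' @param land_t,land_prev `land_account` objects on matched crop sets.
#' @param m a `luc_matrix`.
#' @param tol relative tolerance on total-land conservation.
#' @return list with `emissions_mt` and the hectare `transition` matrix.
#' @export
luc_emissions <- function(land_t, land_prev, m, tol = 1e-6) {
  crops <- rownames(m)
  if (!setequal(names(land_t$hectares), crops) ||
      !setequal(names(land_prev$hectares), crops)) {
    stop("crop sets of the land accounts and LUC matrix do not match",
         call. = FALSE)
  }
  d <- land_t$hectares[crops] - land_prev$hectares[crops]
  if (abs(sum(d)) > tol * max(sum(land_t$hectares), 1)) {
    stop("total land change ", signif(sum(d), 4),
         " ha exceeds the conservation tolerance", call. = FALSE)
  }
  loss <- pmax(-d, 0)
  gain <- pmax(d, 0)
  trans <- matrix(0, length(crops), length(crops),
                  dimnames = list(from = crops, to = crops))
  if (sum(gain) > 0) trans <- outer(loss, gain / sum(gain))
  list(emissions_mt = sum(trans * m) / 1e6, transition = trans)
}
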