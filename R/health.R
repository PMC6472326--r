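# Clinical health outcomes: simulated lookup tables over the cholesterol
# ratio interval [2, 7], degree-10 polynomial evaluators, and conversion of
# biomarker strata into cases, deaths, YLD, time losses and hospital costs.

#' Support values of the clinical lookup tables
#'
#' The 11 end-points of the 10 equidistant sub-intervals of the Total:HDL
#' cholesterol ratio interval \[2.0, 7.0\].
#'
#' @return numeric vector of length 11.
#' @export
lookup_support <- function() seq(2, 7, by = 0.5)

#' Build simulated clinical-outcome lookup tables
#'
#' For every disease x age x gender x location cell and each of the 11
#' support values, the table entry is the mean incidence (and excess
#' mortality) over `n` simulated individuals drawn from the cell's normal
#' biomarker distribution recentred at the support value.  One set of
#' normal deviates is drawn per cell and reused across support values
#' (common random numbers), so monotone risk functions yield monotone
#' tables exactly.
#'
#' @param dists a `biomarker_distributions` object (supplies the standard
#'   deviations).
#' @param risks a `risk_function_set`.
#' @param n number of simulated individuals per cell (>= 100).
#' @param seed integer seed; identical seeds give identical tables.
#' @return object of class `lookup_table_set` with arrays
#'   `incidence` and `mortality` of dim (disease, age, gender, location,
#'   support).
#' @export
build_lookup_tables <- function(dists, risks, n = 10000L, seed = 1L) {
  if (n < 100L) stop("`n` must be at least 100", call. = FALSE)
  dims <- risks$dims
  sup <- lookup_support()
  dn <- list(disease = risks$diseases, age = dims$age_groups,
             gender = dims$genders, location = dims$locations,
             support = as.character(sup))
  inc <- array(0, c(2L, 13L, 2L, 2L, 11L), dn)
  mort <- inc
  with_seed(child_seed(seed, 21L), {
    for (a in 1:13) for (g in 1:2) for (l in 1:2) {
      z <- stats::rnorm(n, 0, dists$sd[a, g, l])
      for (d in 1:2) {
        for (k in seq_along(sup)) {
          cv <- sup[k] + z
          inc[d, a, g, l, k] <- mean(risk_rate(risks, "incidence",
                                               risks$diseases[d], a, g, l,
                                               cv))
          mort[d, a, g, l, k] <- mean(risk_rate(risks, "mortality",
                                                risks$diseases[d], a, g, l,
                                                cv))
        }
      }
    }
  })
  structure(list(incidence = inc, mortality = mort, support = sup,
                 n = n, dims = dims, diseases = risks$diseases),
            class = "lookup_table_set")
}

# Degree-10 interpolation through the 11 nodes on the normalized domain
# [-1, 1]; one step of iterative refinement keeps node errors near machine
# precision despite the equidistant Vandermonde conditioning.
interp_coefficients <- function(y, tnodes) {
  V <- outer(tnodes, 0:(length(tnodes) - 1L), `^`)
  co <- solve(V, y)
  co + solve(V, y - as.numeric(V %*% co))
}

#' Fit degree-10 polynomial evaluators to lookup tables
#'
#' Interpolates each cell's 11 table values exactly with a degree-10
#' polynomial in the normalized coordinate `t = (c - 4.5) / 2.5` (the
#' affine map of \[2, 7\] onto \[-1, 1\]).
#'
#' @param tables a `lookup_table_set`.
#' @return object of class `risk_polynomial_set` with coefficient arrays of
#'   dim (disease, age, gender, location, 11).
#' @export
fit_polynomials <- function(tables) {
  sup <- tables$support
  if (anyDuplicated(sup)) stop("duplicated support values", call. = FALSE)
  tnodes <- (sup - 4.5) / 2.5
  co_inc <- array(0, dim(tables$incidence), dimnames(tables$incidence))
  co_mort <- co_inc
  for (d in 1:2) for (a in 1:13) for (g in 1:2) for (l in 1:2) {
    co_inc[d, a, g, l, ] <- interp_coefficients(tables$incidence[d, a, g, l, ],
                                                tnodes)
    co_mort[d, a, g, l, ] <- interp_coefficients(tables$mortality[d, a, g, l, ],
                                                 tnodes)
  }
  structure(list(incidence = co_inc, mortality = co_mort,
                 support = sup, dims = tables$dims,
                 diseases = tables$diseases),
            class = "risk_polynomial_set")
}

#' Evaluate a fitted risk polynomial
#'
#' Cholesterol values are clamped to \[2, 7\] and outputs to \[0, 1\].
#'
#' @param polys a `risk_polynomial_set`.
#' @param type `"incidence"` or `"mortality"`.
#' @param disease,age_idx,gender_idx,location_idx cell selectors.
#' @param c_values cholesterol ratio values.
#' @return annual rates in \[0, 1\].
#' @export
polynomial_rate <- function(polys, type, disease, age_idx, gender_idx,
                            location_idx, c_values) {
  d <- if (is.character(disease)) match(disease, polys$diseases) else disease
  co <- if (type == "incidence") {
    polys$incidence[d, age_idx, gender_idx, location_idx, ]
  } else {
    polys$mortality[d, age_idx, gender_idx, location_idx, ]
  }
  t <- (pmin(pmax(c_values, 2), 7) - 4.5) / 2.5
  co <- unname(co)
  acc <- rep(co[11L], length(t))
  for (k in 10:1) acc <- acc * t + co[k]
  pmin(pmax(acc, 0), 1)
}

# Fractional working-age weight of each five-year band for a given
# retirement age (working span [15, retirement)).
working_weights <- function(dims, retirement_age) {
  s <- dims$age_starts
  pmax(0, pmin(1, (retirement_age - s) / 5)) * pmax(0, pmin(1, (s + 5 - 15) / 5))
}

#' Convert biomarker strata into clinical outcomes
#'
#' Incident cases are `sum_strata frequency x population-at-risk x
#' incidence rate` per cell; premature deaths use the excess-mortality
#' polynomials.  Aggregates follow: YLD = cases x disability weight x
#' duration (stroke duration capped at the remaining horizon), caregiver
#' work/leisure time per stroke case, hospital costs per case, and patient
#' worktime losses over working-age cases corrected for workforce
#' participation rates.
#'
#' @param strata named list of `biomarker_strata`, one per household.
#' @param polys a `risk_polynomial_set`.
#' @param pop a `population_state`.
#' @param costs a `health_cost_parameters` object.
#' @param horizon_remaining years left to the model horizon (caps the
#'   stroke YLD duration).
#' @return object of class `clinical_outcomes`.
#' @export
evaluate_outcomes <- function(strata, polys, pop, costs,
                              horizon_remaining = Inf) {
  dims <- polys$dims
  nH <- dims$n_households
  cases <- array(0, c(2L, nH, 13L, 2L),
                 dimnames = list(polys$diseases, dims$households,
                                 dims$age_groups, dims$genders))
  deaths <- cases
  excess <- array(0, dim = dim(pop$counts), dimnames = dimnames(pop$counts))
  n_clamped <- 0L
  wwork <- working_weights(dims, costs$retirement_age)
  worktime <- c(mi = 0, stroke = 0)
  for (h in seq_len(nH)) {
    hh <- dims$households[h]
    r <- match(dims$household_region[hh], dims$regions)
    l <- match(dims$household_location[hh], dims$locations)
    st <- strata[[hh]]
    n_clamped <- n_clamped + sum(st$support < 2 | st$support > 7)
    for (d in 1:2) for (g in 1:2) {
      for (a in 1:13) {
        p_at_risk <- pop$counts[r, l, a, g]
        if (p_at_risk <= 0) next
        ri <- sum(st$frequencies *
                    polynomial_rate(polys, "incidence", d, a, g, l,
                                    st$support))
        rm_ <- sum(st$frequencies *
                     polynomial_rate(polys, "mortality", d, a, g, l,
                                     st$support))
        cases[d, h, a, g] <- p_at_risk * ri
        deaths[d, h, a, g] <- min(p_at_risk * rm_, p_at_risk)
        excess[r, l, a, g] <- excess[r, l, a, g] + deaths[d, h, a, g]
        worktime[d] <- worktime[d] + cases[d, h, a, g] * wwork[a] *
          costs$participation[g] * costs$worktime_loss_py[[d]]
      }
    }
  }
  if (n_clamped > 0L) {
    warning(n_clamped, " strata support points outside [2, 7] were clamped",
            call. = FALSE)
  }
  hosp_by_hh <- vapply(seq_len(nH), function(h) {
    sum(cases[1L, h, , ]) * costs$hospital_cost[["mi"]] +
      sum(cases[2L, h, , ]) * costs$hospital_cost[["stroke"]]
  }, numeric(1))
  names(hosp_by_hh) <- dims$households
  total_cases <- c(mi = sum(cases[1L, , , ]), stroke = sum(cases[2L, , , ]))
  total_deaths <- c(mi = sum(deaths[1L, , , ]), stroke = sum(deaths[2L, , , ]))
  dur <- c(mi = costs$duration_mi,
           stroke = min(costs$duration_stroke, horizon_remaining))
  yld <- total_cases * costs$yld_weight * dur
  structure(list(
    cases = cases, deaths = deaths, excess_deaths = excess,
    total_cases = total_cases, total_deaths = total_deaths,
    yld = yld,
    caregiver_work_py = total_cases[["stroke"]] * costs$caregiver_work_py,
    caregiver_leisure_py = total_cases[["stroke"]] *
      costs$caregiver_leisure_py,
    hospital_cost = total_cases * costs$hospital_cost,
    hospital_cost_by_household = hosp_by_hh,
    worktime_loss_py = worktime,
    clamped = n_clamped
  ), class = "clinical_outcomes")
}

#' @export
print.clinical_outcomes <- function(x, ...) {
  cat("<clinical_outcomes> cases:", round(sum(x$total_cases)), "deaths:",
      round(sum(x$total_deaths)), "\n")
  invisible(x)
}
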