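# Model assembly and the counterfactual growth path.

#' Assemble a full simulation model
#'
#' Calibrates the economy from the synthetic truth, builds the Monte-Carlo
#' clinical lookup tables and their polynomial evaluators, calibrates the
#' person-year to labour-endowment conversion, and solves the
#' counterfactual growth path (productivity and price-level shifters per
#' period so that real and nominal GDP grow at the configured rates).
#'
#' @param truth a `synthetic_truth`.
#' @param config a [cge_config()].
#' @param seed seed for the lookup-table simulation.
#' @param lookup_n simulated individuals per lookup cell.
#' @param aids optional replacement demand-system parameters (named list
#'   per household), e.g. re-estimated under elasticity overrides.
#' @param costs optional replacement `health_cost_parameters`.
#' @param horizon optional number of periods (defaults to all).
#' @return object of class `med_health_model`.
#' @export
build_model <- function(truth, config = cge_config(), seed = 1L,
                        lookup_n = 10000L, aids = NULL, costs = NULL,
                        horizon = NULL) {
  params <- calibrate_economy(truth, config, aids = aids)
  costs <- costs %||% truth$cost_parameters
  tables <- build_lookup_tables(truth$biomarker_distributions,
                                truth$risk_functions, n = lookup_n,
                                seed = seed)
  polys <- fit_polynomials(tables)
  model <- structure(list(
    truth = truth, params = params, config = config, costs = costs,
    tables = tables, polys = polys,
    dims = truth$dims,
    horizon = horizon %||% truth$dims$n_periods
  ), class = "med_health_model")
  model$labour_conv <- calibrate_labour_conversion(model)
  model$baseline <- run_baseline(model)
  model
}

#' @export
print.med_health_model <- function(x, ...) {
  cat("<med_health_model>", x$dims$n_commodities, "commodities,",
      x$horizon, "periods; baseline",
      if (is.null(x$baseline)) "not yet solved" else "solved", "\n")
  invisible(x)
}

# Benchmark endowment units per person-year, net of period-1 baseline
# worktime losses so that the benchmark replicates exactly.
calibrate_labour_conversion <- function(model) {
  truth <- model$truth
  oc <- evaluate_outcomes(truth$strata, model$polys, truth$population,
                          model$costs, horizon_remaining = model$horizon)
  losses <- sum(oc$worktime_loss_py) + oc$caregiver_work_py
  ls <- derive_labour_supply(truth$population, model$costs,
                             worktime_losses = losses)
  c(skilled = unname(model$params$FS0[["labour_skilled"]] / ls$skilled),
    unskilled = unname(model$params$FS0[["labour_unskilled"]] /
                         ls$unskilled))
}

# Health outcome levels and the labour/hospital feedback magnitudes for a
# given strata set, population and period.
health_block <- function(model, strata, pop, t) {
  oc <- evaluate_outcomes(strata, model$polys, pop, model$costs,
                          horizon_remaining = model$horizon - t + 1)
  losses <- sum(oc$worktime_loss_py) + oc$caregiver_work_py
  ls <- derive_labour_supply(pop, model$costs, worktime_losses = losses)
  list(outcomes = oc, losses = losses, labour = ls,
       hospital = sum(oc$hospital_cost))
}

#' Solve the counterfactual (baseline) growth path
#'
#' Period 1 replicates the benchmark.  For later periods a Hicks-neutral
#' productivity shifter is root-solved so realized real GDP matches the
#' configured real growth rate, and the price-level shifter is rescaled
#' analytically so nominal GDP matches the nominal rate exactly (the model
#' is homogeneous of degree one in the price level).  Demography, baseline
#' clinical outcomes and land use are advanced alongside.
#'
#' @param model a `med_health_model` (the baseline slot may be unset).
#' @param horizon number of periods to run.
#' @return list of per-period records (class `baseline_trajectory`).
#' @export
run_baseline <- function(model, horizon = model$horizon) {
  params <- model$params
  truth <- model$truth
  gt <- truth$growth_targets
  state <- initial_state(params)
  pop <- truth$population
  strata <- truth$strata
  crops <- model$dims$crops
  periods <- list()
  x_prev <- NULL
  land_prev <- NULL
  ghg_cum <- 0
  for (t in seq_len(horizon)) {
    hb <- health_block(model, strata, pop, t)
    if (t > 1L) {
      state$FS[["labour_skilled"]] <- hb$labour$skilled *
        model$labour_conv[["skilled"]]
      state$FS[["labour_unskilled"]] <- hb$labour$unskilled *
        model$labour_conv[["unskilled"]]
      state$fsav <- params$fsav0 * (1 + gt$nominal)^(t - 1)
      state$pfac <- (1 + gt$nominal)^(t - 1)
    }
    closure <- closure_spec("baseline")
    if (t == 1L) {
      eq <- solve_equilibrium(params, state, closure)
    } else {
      target_real <- params$gdp0 * (1 + gt$real)^(t - 1)
      tfp_guess <- state$tfp
      solve_at <- function(tfp) {
        st <- state
        st$tfp <- tfp
        solve_equilibrium(params, st, closure, x0 = x_prev)
      }
      g <- function(tfp) log(solve_at(tfp)$gdp_real / target_real)
      lo <- tfp_guess * 0.97
      hi <- tfp_guess * 1.12
      glo <- g(lo)
      ghi <- g(hi)
      tries <- 0L
      while (glo > 0 && tries < 8L) { lo <- lo * 0.9; glo <- g(lo); tries <- tries + 1L }
      while (ghi < 0 && tries < 16L) { hi <- hi * 1.1; ghi <- g(hi); tries <- tries + 1L }
      if (glo > 0 || ghi < 0) {
        stop("baseline growth shifter solve failed in period ", t,
             call. = FALSE)
      }
      root <- bracket_root(g, lo, hi, tol = 1e-9, f_lower = glo,
                           f_upper = ghi)
      state$tfp <- root$root
      eq <- solve_at(state$tfp)
      # exact nominal rescale via price-level homogeneity
      target_nom <- params$gdp0 * (1 + gt$nominal)^(t - 1)
      lam <- target_nom / eq$gdp_nom
      if (abs(lam - 1) > 1e-12) {
        nC <- model$dims$n_commodities
        nF <- length(model$dims$factors)
        x <- eq$x
        pr_idx <- c(seq_len(nC), 2 * nC + seq_len(nF + 1L))
        x[pr_idx] <- x[pr_idx] + log(lam)
        state$pfac <- state$pfac * lam
        eq <- solve_equilibrium(params, state, closure, x0 = x)
      }
    }
    x_prev <- eq$x
    land <- land_allocation(eq$qf["land", crops], eq$qa[crops],
                            truth$hectares0)
    ghg <- if (is.null(land_prev)) 0 else
      luc_emissions(land, land_prev, truth$luc_matrix)$emissions_mt
    ghg_cum <- ghg_cum + ghg
    intake <- household_intakes(model, eq, pop)
    periods[[t]] <- list(t = t, eq = eq, state = state, pop = pop,
                         strata = strata, health = hb, land = land,
                         ghg_flow = ghg, ghg_cum = ghg_cum,
                         intake = intake)
    land_prev <- land
    pop <- project_population(pop, hb$outcomes$excess_deaths)
    state <- step_dynamics(state, eq, params, hb$labour, model$labour_conv)
  }
  structure(periods, class = "baseline_trajectory")
}

# Per-household energy intakes and the national per-capita palm-oil energy.
household_intakes <- function(model, eq, pop) {
  dims <- model$dims
  hp <- household_population(dims, pop)
  out <- lapply(stats::setNames(dims$households, dims$households),
                function(h) {
    intake_from_consumption(eq$qh[, h], model$truth$nutrient_coefficients,
                            h, hp[h])
  })
  palm <- dims$palm_oil
  ed <- model$truth$nutrient_coefficients$energy_density[palm, ]
  palm_pc <- sum(eq$qh[palm, ] * ed) / (sum(hp) * 365)
  energies <- vapply(out, `[[`, numeric(1), "energy")
  shares <- vapply(out, `[[`, numeric(3), "shares")  # 3 x nH
  nat_shares <- as.numeric(shares %*% (energies * hp)) /
    sum(energies * hp)
  names(nat_shares) <- c("sfa", "mufa", "pufa")
  list(by_household = out, palm_energy_pc = palm_pc,
       national_shares = nat_shares, household_population = hp)
}
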