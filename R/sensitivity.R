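# Sensitivity suites: biomarker coefficient bounds, labour-market
# parameters, palm-oil demand elasticities, and iso-consumption closures.

#' Run a sensitivity suite
#'
#' Suites: `"biomarker_bounds"` (the four bound combinations of the
#' cholesterol coefficients: both extremes, a uniform and a diverse
#' scenario), `"participation"` (uniform workforce participation rates,
#' default grid 65--80%), `"retirement"` (retirement age 59 and 69),
#' `"own_price"` (palm-oil own-price elasticity, default -0.75..-1.15),
#' `"cross_price"` (palm/other-oils cross-price elasticity, default
#' 0.00..0.25), `"income"` (palm-oil income elasticity, default
#' 0.90..1.30), `"iso_consumption"` (the three compensating-transfer
#' closure variants).  Elasticity suites re-estimate the demand system
#' under regularity, rebuild the baseline and (optionally) re-solve the
#' tax rate; labour suites rebuild the baseline with modified cost
#' parameters; the biomarker and closure suites re-run the scenario only.
#' Grid-point failures are caught and reported without aborting the rest.
#'
#' @param model a `med_health_model`.
#' @param suite suite label (see above).
#' @param tax_rate sales tax rate to impose (required unless re-solved).
#' @param opts a [scenario_options()] object.
#' @param grid optional replacement grid.
#' @param resolve_tax re-solve the tax rate at demand-altering grid
#'   points (default `TRUE` for the elasticity suites).
#' @return list of class `sensitivity_grid`: one entry per grid point with
#'   `label`, `value`, and `result` (a `scenario_result`) or `error`.
#' @export
run_sensitivity <- function(model, suite, tax_rate = NULL,
                            opts = scenario_options(), grid = NULL,
                            resolve_tax = NULL) {
  suites <- c("biomarker_bounds", "participation", "retirement",
              "own_price", "cross_price", "income", "iso_consumption")
  if (!suite %in% suites) {
    stop("unknown suite; must be one of: ", paste(suites, collapse = ", "),
         call. = FALSE)
  }
  resolve_tax <- resolve_tax %||%
    (suite %in% c("own_price", "cross_price", "income"))
  run_point <- function(label, value, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      list(label = label, value = value, error = conditionMessage(res))
    } else {
      list(label = label, value = value, result = res)
    }
  }
  pts <- switch(suite,
    biomarker_bounds = {
      co <- opts$coeffs
      combos <- list(
        upper = co$upper,
        lower = co$lower,
        uniform = c(co$upper[["sfa"]], co$lower[["mufa"]],
                    co$lower[["pufa"]]),
        diverse = c(co$lower[["sfa"]], co$upper[["mufa"]],
                    co$upper[["pufa"]])
      )
      lapply(names(combos), function(nm) {
        run_point(nm, combos[[nm]], function() {
          o <- opts
          o$bound <- stats::setNames(combos[[nm]], c("sfa", "mufa", "pufa"))
          run_scenario(model, tax_rate, o)
        })
      })
    },
    participation = {
      g <- grid %||% c(0.65, 0.70, 0.75, 0.80)
      lapply(g, function(p) {
        run_point(paste0("participation_", p), p, function() {
          costs <- model$costs
          costs$participation[] <- p
          m <- rebuild_model(model, costs = costs)
          run_scenario(m, tax_rate, opts)
        })
      })
    },
    retirement = {
      g <- grid %||% c(59, 69)
      lapply(g, function(ra) {
        run_point(paste0("retirement_", ra), ra, function() {
          costs <- model$costs
          costs$retirement_age <- ra
          m <- rebuild_model(model, costs = costs)
          run_scenario(m, tax_rate, opts)
        })
      })
    },
    own_price = {
      g <- grid %||% seq(-0.75, -1.15, length.out = 5)
      lapply(g, function(v) {
        run_point(paste0("own_price_", v), v, function() {
          m <- rebuild_with_elasticities(model, function(eps, eta, dims) {
            ipm <- dims$commodities == dims$palm_oil
            eps[ipm, ipm] <- v
            list(eps = eps, eta = eta)
          })
          sensitivity_scenario(m, tax_rate, opts, resolve_tax)
        })
      })
    },
    cross_price = {
      g <- grid %||% seq(0, 0.25, length.out = 6)
      lapply(g, function(v) {
        run_point(paste0("cross_price_", v), v, function() {
          m <- rebuild_with_elasticities(model, function(eps, eta, dims) {
            ipm <- dims$commodities == dims$palm_oil
            iol <- dims$commodities == dims$other_oils
            eps[iol, ipm] <- v
            list(eps = eps, eta = eta)
          })
          sensitivity_scenario(m, tax_rate, opts, resolve_tax)
        })
      })
    },
    income = {
      g <- grid %||% seq(0.90, 1.30, length.out = 5)
      lapply(g, function(v) {
        run_point(paste0("income_", v), v, function() {
          m <- rebuild_with_elasticities(model, function(eps, eta, dims) {
            eta[dims$commodities == dims$palm_oil] <- v
            list(eps = eps, eta = eta)
          })
          sensitivity_scenario(m, tax_rate, opts, resolve_tax)
        })
      })
    },
    iso_consumption = {
      variants <- grid %||% c("iso_budget", "iso_real", "iso_both")
      lapply(variants, function(v) {
        run_point(v, v, function() {
          o <- opts
          o$closure_variant <- v
          run_scenario(model, tax_rate, o)
        })
      })
    })
  structure(list(suite = suite, points = pts), class = "sensitivity_grid")
}

sensitivity_scenario <- function(m, tax_rate, opts, resolve_tax) {
  tau <- if (resolve_tax) find_tax_rate(m, opts)$tax_rate else tax_rate
  res <- run_scenario(m, tau, opts)
  res$tax_rate <- tau
  res
}

# Rebuild a model keeping the expensive pieces configurable.
rebuild_model <- function(model, aids = NULL, costs = NULL) {
  build_model(model$truth, config = model$config,
              seed = attr(model$tables, "seed") %||% 1L,
              lookup_n = model$tables$n,
              aids = aids %||% model$params$aids,
              costs = costs %||% model$costs,
              horizon = model$horizon)
}

# Apply an elasticity modification to every household's truth demand
# system, re-impose regularity, and rebuild the model.
rebuild_with_elasticities <- function(model, modify) {
  dims <- model$dims
  aids_new <- lapply(model$truth$aids_parameters, function(p) {
    el <- aids_elasticities(p)
    mod <- modify(el$price, el$income, dims)
    priors <- structure(list(eps = mod$eps, eta = mod$eta,
                             shares = p$shares0,
                             expenditure0 = exp(p$alpha0)),
                        class = "elasticity_priors")
    estimate_aids(elasticities_to_aids(priors))
  })
  rebuild_model(model, aids = aids_new)
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("<sensitivity_grid>", x$suite, "with", length(x$points), "points (",
      sum(vapply(x$points, function(p) is.null(p$error), logical(1))),
      "solved )\n")
  invisible(x)
}
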