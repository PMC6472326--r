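# Scenario engine: well-posedness, decomposition, closures, sensitivity
# mechanics and reporting.

test_that("a zero-magnitude policy equals the baseline identically", {
  model <- test_model()
  s0 <- run_scenario(model, 0)
  expect_identical(max(abs(s0$delta)), 0)
})

test_that("scenario runs are deterministic", {
  model <- small_model()
  a <- suppressWarnings(run_scenario(model, 0.6))
  b <- suppressWarnings(run_scenario(model, 0.6))
  expect_identical(a$indicators, b$indicators)
})

test_that("pathway decomposition is additive and freezes the biomarker", {
  dec <- test_decomposition()
  expect_identical(dec$total$delta - dec$tax_only$delta,
                   dec$health_pathway)
  # the frozen run has no biomarker or clinical deviation at all
  expect_equal(max(abs(dec$tax_only$delta[, c("chol_mean", "cases_mi",
                                              "cases_stroke", "deaths_mi",
                                              "deaths_stroke")])), 0,
               tolerance = 1e-9)
  # hence the health pathway carries the total's biomarker response
  expect_equal(dec$health_pathway[, "chol_mean"],
               dec$total$delta[, "chol_mean"], tolerance = 1e-12)
})

test_that("the solved tax reproduces the documented qualitative sign pattern", {
  model <- test_model()
  run <- test_policy_run()
  hz <- model$horizon
  expect_lt(run$delta[hz, "palm_energy_pc"], 0)
  expect_lt(run$delta[hz, "sfa_share"], 0)
  expect_lt(run$delta[hz, "chol_mean"], 0)
  expect_lt(sum(run$delta[, "cases_mi"] + run$delta[, "cases_stroke"]), 0)
  expect_gt(run$delta[hz, "ghg_cum_mt"], 0)
  # saved lives expand population and the workforce
  expect_gt(run$delta[hz, "population"], 0)
  expect_gt(run$delta[hz, "workforce_py"], 0)
})

test_that("find_tax_rate hits the intake target on re-simulation", {
  model <- test_model()
  sol <- test_tax()
  run <- suppressWarnings(run_scenario(model, sol$tax_rate))
  hz <- model$horizon
  achieved <- 1 - run$periods[[hz]]$intake$palm_energy_pc /
    model$baseline[[hz]]$intake$palm_energy_pc
  expect_lt(abs(achieved - 0.5) / 0.5, 1e-3)
  expect_gt(sol$tax_rate, 0)
  expect_true(nrow(sol$trace) >= 2)
})

test_that("a zero target needs no tax", {
  model <- small_model()
  sol <- find_tax_rate(model, scenario_options(target = 0))
  expect_identical(sol$tax_rate, 0)
})

test_that("iso-real-consumption holds household consumption at baseline", {
  model <- small_model()
  res <- suppressWarnings(
    run_scenario(model, 0.6, scenario_options(closure_variant = "iso_real"))
  )
  cols <- paste0("cons_real_", model$dims$households)
  rel <- abs(res$delta[, cols]) /
    res$baseline_indicators[, cols]
  expect_lt(max(rel), 1e-6)
})

test_that("biomarker coefficient bounds bracket the central health effect", {
  model <- test_model()
  tau <- test_tax()$tax_rate
  grid <- suppressWarnings(
    run_sensitivity(model, "biomarker_bounds", tax_rate = tau)
  )
  res <- stats::setNames(lapply(grid$points, `[[`, "result"),
                         vapply(grid$points, `[[`, "", "label"))
  expect_true(all(!vapply(grid$points, function(p) !is.null(p$error),
                          logical(1))))
  central <- test_policy_run()
  hz <- model$horizon
  chol <- vapply(res, function(r) r$delta[hz, "chol_mean"], numeric(1))
  # upper-bound coefficients give the weakest decline, lower the strongest
  expect_true(chol[["lower"]] <= central$delta[hz, "chol_mean"] &&
                central$delta[hz, "chol_mean"] <= chol[["upper"]])
  cases <- vapply(res, function(r) sum(r$delta[, "cases_mi"] +
                                         r$delta[, "cases_stroke"]),
                  numeric(1))
  cen_cases <- sum(central$delta[, "cases_mi"] +
                     central$delta[, "cases_stroke"])
  expect_true(min(cases) <= cen_cases && cen_cases <= max(cases))
})

test_that("degenerate sensitivity grids collapse to the default run", {
  model <- small_model()
  grid <- suppressWarnings(
    run_sensitivity(model, "participation", tax_rate = 0.6,
                    grid = unname(model$costs$participation[["male"]]))
  )
  expect_length(grid$points, 1)
  expect_null(grid$points[[1]]$error)
  expect_error(run_sensitivity(model, "nonsense", 0.1), "unknown suite")
})

test_that("indicator deltas vanish continuously as the tax goes to zero", {
  model <- small_model()
  big <- suppressWarnings(run_scenario(model, 0.6))
  tiny <- suppressWarnings(run_scenario(model, 1e-6))
  scale <- apply(abs(big$delta), 2, max)
  live <- scale > 1e-8
  expect_true(all(apply(abs(tiny$delta[, live]), 2, max) <=
                    1e-4 * scale[live] + 1e-12))
})

test_that("the hospital-cost payer switch moves the burden off government", {
  model <- small_model()
  gov <- suppressWarnings(run_scenario(model, 0.6))
  hh <- suppressWarnings(
    run_scenario(model, 0.6, scenario_options(hospital_payer = "households"))
  )
  # with households paying, real government consumption stays on the
  # counterfactual path exactly
  expect_equal(max(abs(hh$delta[, "gov_real"])), 0, tolerance = 1e-12)
  expect_gt(max(abs(gov$delta[, "gov_real"])), 0)
  # households receive the saved hospital costs as a lump-sum transfer
  expect_gt(sum(hh$periods[[3]]$eq$TRH), 0)
  expect_error(scenario_options(hospital_payer = "insurer"), "payer")
})

test_that("indicator reports are definitionally consistent", {
  model <- small_model()
  s0 <- run_scenario(model, 0)
  tab0 <- report_indicators(s0)
  expect_true(all(tab0$cumulative == 0))
  expect_true(all(tab0$longrun == 0))
  run <- suppressWarnings(run_scenario(model, 0.6))
  tab <- report_indicators(run)
  b <- run$baseline_indicators
  i <- match("gdp_real", tab$indicator)
  expect_equal(tab$cumulative[i], sum(run$delta[, "gdp_real"]),
               tolerance = 1e-12)
  expect_equal(tab$cumulative_pct[i],
               sum(run$delta[, "gdp_real"]) / sum(b[, "gdp_real"]) * 100,
               tolerance = 1e-10)
  hz <- nrow(run$delta)
  expect_equal(tab$longrun[i], run$delta[hz, "gdp_real"],
               tolerance = 1e-12)
  traj <- tidy_trajectory(run)
  expect_equal(nrow(traj), nrow(run$indicators) * ncol(run$indicators))
  expect_equal(traj$delta, traj$scenario - traj$baseline)
})
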