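# Simulated lookup tables, polynomial evaluators and outcome accounting.

test_that("lookup tables are reproducible and monotone", {
  tr <- test_gen()$truth
  t1 <- build_lookup_tables(tr$biomarker_distributions, tr$risk_functions,
                            n = 1000, seed = 8)
  t2 <- build_lookup_tables(tr$biomarker_distributions, tr$risk_functions,
                            n = 1000, seed = 8)
  expect_identical(t1, t2)
  mono <- apply(t1$incidence, 1:4, function(v) all(diff(v) >= -1e-15))
  expect_true(all(mono))
  expect_true(all(t1$incidence >= 0 & t1$incidence <= 1))
  expect_error(build_lookup_tables(tr$biomarker_distributions,
                                   tr$risk_functions, n = 50), "at least")
})

test_that("degenerate biomarker spread recovers the raw risk function", {
  tr <- test_gen()$truth
  dists <- tr$biomarker_distributions
  dists$sd[] <- 1e-9
  tab <- build_lookup_tables(dists, tr$risk_functions, n = 500, seed = 2)
  sup <- lookup_support()
  for (k in c(1, 6, 11)) {
    expect_equal(tab$incidence[1, 13, 1, 1, k],
                 risk_rate(tr$risk_functions, "incidence", "mi", 13, 1, 1,
                           sup[k]),
                 tolerance = 1e-6)
  }
})

test_that("the 10,000-draw table agrees with a million-draw oracle", {
  tr <- test_gen()$truth
  tab <- build_lookup_tables(tr$biomarker_distributions, tr$risk_functions,
                             n = 10000, seed = 5)
  a <- 12; g <- 1; l <- 2; k <- 6
  sdv <- tr$biomarker_distributions$sd[a, g, l]
  set.seed(1234)
  z <- rnorm(1e6, 0, sdv)
  vals <- risk_rate(tr$risk_functions, "incidence", "mi", a, g, l,
                    lookup_support()[k] + z)
  se <- stats::sd(vals) / sqrt(10000)
  expect_lt(abs(tab$incidence[1, a, g, l, k] - mean(vals)), 4 * se)
})

test_that("degree-10 interpolation is exact at the nodes", {
  tr <- test_gen()$truth
  tab <- build_lookup_tables(tr$biomarker_distributions, tr$risk_functions,
                             n = 400, seed = 3)
  polys <- fit_polynomials(tab)
  sup <- lookup_support()
  worst <- 0
  for (d in 1:2) for (a in c(1, 7, 13)) for (g in 1:2) for (l in 1:2) {
    got <- polynomial_rate(polys, "incidence", d, a, g, l, sup)
    worst <- max(worst, max(abs(got - tab$incidence[d, a, g, l, ])))
  }
  expect_lt(worst, 1e-10)
})

test_that("constant and quadratic tables are represented exactly", {
  tr <- test_gen()$truth
  tab <- build_lookup_tables(tr$biomarker_distributions, tr$risk_functions,
                             n = 200, seed = 4)
  # constant cell
  tab$incidence[1, 1, 1, 1, ] <- 0.37
  # quadratic cell on [2, 7]
  qf <- function(c) 0.01 + 0.002 * (c - 2) + 0.0005 * (c - 2)^2
  tab$incidence[2, 1, 1, 1, ] <- qf(tab$support)
  polys <- fit_polynomials(tab)
  expect_lt(max(abs(polys$incidence[1, 1, 1, 1, -1])), 1e-12)
  grid <- seq(2, 7, by = 0.01)
  expect_lt(max(abs(polynomial_rate(polys, "incidence", 2, 1, 1, 1, grid) -
                      qf(grid))), 1e-8)
  tab$support[2] <- tab$support[1]
  expect_error(fit_polynomials(tab), "duplicated")
})

test_that("outcome accounting matches hand arithmetic", {
  tr <- test_gen()$truth
  d <- tr$dims
  tab <- build_lookup_tables(tr$biomarker_distributions, tr$risk_functions,
                             n = 300, seed = 6)
  polys <- fit_polynomials(tab)
  pop <- tr$population
  # zero population: all outcomes vanish
  pop0 <- pop
  pop0$counts[] <- 0
  oc0 <- evaluate_outcomes(tr$strata, polys, pop0, tr$cost_parameters)
  expect_equal(sum(oc0$total_cases), 0)
  expect_equal(sum(oc0$total_deaths), 0)
  expect_equal(sum(oc0$hospital_cost), 0)
  # single-stratum household: cases = freq x pop x rate per cell
  strata1 <- tr$strata
  for (h in d$households) strata1[[h]] <- new_strata(4.2, 1)
  oc1 <- evaluate_outcomes(strata1, polys, pop, tr$cost_parameters)
  h <- d$households[1]
  r <- match(d$household_region[h], d$regions)
  l <- match(d$household_location[h], d$locations)
  a <- 10; g <- 2
  hand <- pop$counts[r, l, a, g] *
    polynomial_rate(polys, "incidence", 1, a, g, l, 4.2)
  expect_equal(oc1$cases[1, h, a, g], hand, tolerance = 1e-12)
  # strata shifts move outcomes monotonically, and the deviation changes
  # sign with the direction of the biomarker shift
  oc_base <- evaluate_outcomes(tr$strata, polys, pop, tr$cost_parameters)
  strata_up <- lapply(tr$strata, shift_strata, delta_c = 0.5)
  strata_dn <- lapply(tr$strata, shift_strata, delta_c = -0.5)
  oc_up <- evaluate_outcomes(strata_up, polys, pop, tr$cost_parameters)
  oc_dn <- evaluate_outcomes(strata_dn, polys, pop, tr$cost_parameters)
  expect_true(all(oc_up$total_cases >= oc_base$total_cases - 1e-9))
  expect_true(all(oc_dn$total_cases <= oc_base$total_cases + 1e-9))
  expect_gt(sum(oc_up$total_cases) - sum(oc_base$total_cases), 0)
  expect_lt(sum(oc_dn$total_cases) - sum(oc_base$total_cases), 0)
})

test_that("aggregate outcome conversions use the cost parameters", {
  tr <- test_gen()$truth
  tab <- build_lookup_tables(tr$biomarker_distributions, tr$risk_functions,
                             n = 300, seed = 6)
  polys <- fit_polynomials(tab)
  costs <- tr$cost_parameters
  oc <- evaluate_outcomes(tr$strata, polys, tr$population, costs,
                          horizon_remaining = 3)
  expect_equal(unname(oc$yld[["stroke"]]),
               unname(oc$total_cases[["stroke"]] * costs$yld_weight[["stroke"]] *
                        min(costs$duration_stroke, 3)),
               tolerance = 1e-12)
  expect_equal(oc$caregiver_work_py,
               oc$total_cases[["stroke"]] * costs$caregiver_work_py,
               tolerance = 1e-12)
  expect_equal(unname(oc$hospital_cost[["mi"]]),
               unname(oc$total_cases[["mi"]] * costs$hospital_cost[["mi"]]),
               tolerance = 1e-12)
})
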