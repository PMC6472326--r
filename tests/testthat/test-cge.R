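# Within-period equilibrium, closures and recursive dynamics.

test_that("the zero-shock model replicates the benchmark SAM flows", {
  model <- test_model()
  tr <- model$truth
  eq <- model$baseline[[1]]$eq
  b <- tr$benchmark
  expect_lt(max(abs(eq$qa - b$QA) / b$QA), 1e-8)
  expect_lt(max(abs(eq$pdd - 1)), 1e-10)
  expect_lt(max(abs(eq$EH - b$EH) / b$EH), 1e-8)
  expect_lt(max(abs(eq$qh - sweep(b$theta, 2, b$EH, `*`))) / max(b$EH),
            1e-8)
  expect_lt(max(abs(eq$qe - b$E)) / max(b$QA), 1e-8)
  expect_lt(max(abs(eq$qm - b$M)) / max(b$QA), 1e-8)
  expect_lt(max(abs(rowSums(eq$qf) - b$YF) / b$YF), 1e-8)
  expect_equal(eq$gdp_real, b$gdp, tolerance = 1e-8)
})

test_that("Walras's law and institutional accounts close every period", {
  model <- test_model()
  for (p in model$baseline) {
    expect_lt(abs(p$eq$walras_residual), 1e-6)
    expect_lt(max(audit_equilibrium(p$eq, model$params)), 1e-8)
  }
})

test_that("the baseline hits the real and nominal growth targets", {
  model <- test_model()
  gr <- vapply(model$baseline, function(p) p$eq$gdp_real, numeric(1))
  gn <- vapply(model$baseline, function(p) p$eq$gdp_nom, numeric(1))
  gt <- model$truth$growth_targets
  expect_equal(diff(log(gr)), rep(log(1 + gt$real), length(gr) - 1),
               tolerance = 1e-6)
  expect_equal(diff(log(gn)), rep(log(1 + gt$nominal), length(gn) - 1),
               tolerance = 1e-6)
})

test_that("a palm-oil sales tax obeys the demand law in every household", {
  model <- test_model()
  d <- model$dims
  eq0 <- model$baseline[[1]]$eq
  ts <- rep(0, d$n_commodities)
  ip <- d$commodities == d$palm_oil
  ts[ip] <- 0.4
  st <- initial_state(model$params)
  cl <- closure_spec("policy", ts = ts, QG = eq0$QG, sg_target = eq0$SG)
  eq1 <- solve_equilibrium(model$params, st, cl,
                           x0 = c(eq0$x[-length(eq0$x)], 0))
  expect_gt(eq1$pc[ip] / eq0$pc[ip], 1.2)
  for (h in d$households) {
    el <- aids_elasticities(model$params$aids[[h]])
    if (el$price[ip, ip] < 0) {
      expect_lt(eq1$qh[ip, h], eq0$qh[ip, h])
    }
  }
})

test_that("the equilibrium is homogeneous of degree zero in real terms", {
  model <- test_model()
  st <- initial_state(model$params)
  eq0 <- model$baseline[[1]]$eq
  st2 <- st
  st2$pfac <- 2   # doubles the numeraire anchor; fsav is foreign-currency
  eq2 <- solve_equilibrium(model$params, st2)
  expect_equal(eq2$qa, eq0$qa, tolerance = 1e-9)
  expect_equal(eq2$qh, eq0$qh, tolerance = 1e-9)
  expect_equal(eq2$pdd / eq0$pdd, rep(2, model$dims$n_commodities),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(eq2$exr / eq0$exr), 2, tolerance = 1e-9)
})

test_that("capital accumulation honours its boundary and steady state", {
  model <- test_model()
  params <- model$params
  st <- initial_state(params)
  cfg <- params$config
  fake_labour <- list(skilled = 1, unskilled = 1)
  conv <- c(skilled = 1, unskilled = 1)
  # delta = 1 with zero investment violates capital positivity
  params_bad <- params
  params_bad$config$delta <- 1
  eq_zero <- list(qinv = stats::setNames(rep(0, model$dims$n_commodities),
                                         model$dims$commodities))
  expect_error(step_dynamics(st, eq_zero, params_bad, fake_labour, conv),
               "non-positive")
  # investment equal to depreciation keeps the stock constant
  eq_ss <- list(qinv = stats::setNames(
    rep(cfg$delta * st$capital / model$dims$n_commodities,
        model$dims$n_commodities), model$dims$commodities))
  st2 <- step_dynamics(st, eq_ss, params, fake_labour, conv)
  expect_equal(st2$capital, st$capital, tolerance = 1e-12)
  # worktime losses reduce the endowment one-for-one in person-years
  truth <- model$truth
  ls0 <- derive_labour_supply(truth$population, model$costs, 0)
  ls1 <- derive_labour_supply(truth$population, model$costs, 100)
  stA <- step_dynamics(st, eq_ss, params, ls0, model$labour_conv)
  stB <- step_dynamics(st, eq_ss, params, ls1, model$labour_conv)
  dpy <- (stA$FS[["labour_skilled"]] - stB$FS[["labour_skilled"]]) /
    model$labour_conv[["skilled"]] +
    (stA$FS[["labour_unskilled"]] - stB$FS[["labour_unskilled"]]) /
    model$labour_conv[["unskilled"]]
  expect_equal(dpy, 100, tolerance = 1e-8)
})

test_that("full-scale dimensions generate and replicate the benchmark", {
  d <- model_dims("full")
  expect_equal(d$n_commodities, 49L)
  expect_equal(d$n_households, 9L)
  expect_length(d$crops, 7L)
  gen <- generate_synthetic_economy(d, seed = 2)
  expect_true(is_balanced_sam(gen$truth$balanced_sam))
  params <- calibrate_economy(gen$truth)
  eq <- solve_equilibrium(params, initial_state(params))
  expect_lt(max(abs(eq$qa - gen$truth$benchmark$QA) /
                  gen$truth$benchmark$QA), 1e-8)
  expect_lt(abs(eq$walras_residual), 1e-6)
})

test_that("rebuilding the baseline with the same inputs is bit-identical", {
  gen <- generate_synthetic_economy(test_dims(), seed = 7)
  m1 <- build_model(gen$truth, seed = 7, lookup_n = 400L, horizon = 4L)
  m2 <- build_model(gen$truth, seed = 7, lookup_n = 400L, horizon = 4L)
  i1 <- vapply(m1$baseline, function(p) p$eq$gdp_nom, numeric(1))
  i2 <- vapply(m2$baseline, function(p) p$eq$gdp_nom, numeric(1))
  expect_identical(i1, i2)
  expect_identical(m1$baseline[[4]]$eq$x, m2$baseline[[4]]$eq$x)
})
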