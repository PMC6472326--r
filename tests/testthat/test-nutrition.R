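# Energy-intake accounting and the fatty-acid / cholesterol-ratio link.

test_that("single-commodity diets reproduce the commodity's fractions", {
  tr <- test_gen()$truth
  d <- tr$dims
  h <- d$households[1]
  q <- stats::setNames(rep(0, d$n_commodities), d$commodities)
  q[d$palm_oil] <- 10
  it <- intake_from_consumption(q, tr$nutrient_coefficients, h, 1000)
  nc <- tr$nutrient_coefficients
  expect_equal(unname(it$shares["sfa"]), nc$sfa[d$palm_oil, h] * 100,
               tolerance = 1e-12)
  expect_equal(unname(it$shares["pufa"]), nc$pufa[d$palm_oil, h] * 100,
               tolerance = 1e-12)
})

test_that("intake shares are intensive and handle degenerate inputs", {
  tr <- test_gen()$truth
  d <- tr$dims
  h <- d$households[2]
  q <- tr$benchmark$theta[, h] * tr$benchmark$EH[h]
  a <- intake_from_consumption(q, tr$nutrient_coefficients, h, 5e5)
  b <- intake_from_consumption(2 * q, tr$nutrient_coefficients, h, 1e6)
  expect_equal(a$shares, b$shares, tolerance = 1e-12)
  expect_equal(a$energy, b$energy, tolerance = 1e-12)
  expect_error(intake_from_consumption(q * 0, tr$nutrient_coefficients, h,
                                       1000), "zero")
  expect_error(intake_from_consumption(q - 10, tr$nutrient_coefficients, h,
                                       1000), "non-negative")
})

test_that("a three-commodity worked table matches hand-summed energies", {
  d <- test_dims()
  tr <- test_gen()$truth
  h <- d$households[1]
  nc <- tr$nutrient_coefficients
  q <- stats::setNames(rep(0, d$n_commodities), d$commodities)
  picks <- c(d$palm_oil, d$other_oils, "other_food")
  q[picks] <- c(3, 5, 7)
  popn <- 1234
  it <- intake_from_consumption(q, nc, h, popn)
  hand_total <- sum(q[picks] * nc$energy_density[picks, h]) / (popn * 365)
  hand_sfa <- sum(q[picks] * nc$energy_density[picks, h] *
                    nc$sfa[picks, h]) / (popn * 365)
  expect_equal(it$energy, hand_total, tolerance = 1e-12)
  expect_equal(it$sfa, hand_sfa, tolerance = 1e-12)
  expect_equal(unname(it$shares["sfa"]), hand_sfa / hand_total * 100,
               tolerance = 1e-12)
})

test_that("cholesterol response uses the established central coefficients", {
  expect_identical(delta_cholesterol(0, 0, 0), 0)
  expect_equal(delta_cholesterol(1, 0, 0), 0.003)
  expect_equal(delta_cholesterol(0, 1, 0), -0.026)
  expect_equal(delta_cholesterol(0, 0, 1), -0.032)
  # worked long-run share deltas (one-period direct effect)
  expect_equal(delta_cholesterol(-0.322, -0.164, 0.298), -0.006238,
               tolerance = 1e-12)
})

test_that("the cholesterol response is linear", {
  set.seed(4)
  co <- cholesterol_coefficients()
  for (i in 1:1000) {
    x <- rnorm(3); y <- rnorm(3); a <- rnorm(1); b <- rnorm(1)
    lhs <- delta_cholesterol(a * x[1] + b * y[1], a * x[2] + b * y[2],
                             a * x[3] + b * y[3], co)
    rhs <- a * delta_cholesterol(x[1], x[2], x[3], co) +
      b * delta_cholesterol(y[1], y[2], y[3], co)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("coefficient bounds must bracket the central values", {
  expect_error(cholesterol_coefficients(lower = c(0.004, -0.03, -0.04)),
               "bracket")
  co <- cholesterol_coefficients()
  expect_true(all(co$lower <= co$central & co$central <= co$upper))
})

test_that("strata shifts move every support point and preserve structure", {
  st <- new_strata(c(3.0, 4.0), c(0.5, 0.5))
  expect_identical(shift_strata(st, 0), st)
  s2 <- shift_strata(st, 0.5)
  expect_equal(s2$support, c(3.5, 4.5))
  expect_equal(s2$frequencies, st$frequencies)
  # additivity of sequential shifts
  s3 <- shift_strata(shift_strata(st, 0.2), -0.7)
  expect_equal(s3$support, shift_strata(st, -0.5)$support, tolerance = 1e-15)
  # mean shifts by exactly delta under any frequencies
  stw <- new_strata(c(2.5, 3.5, 5.0), c(0.2, 0.5, 0.3))
  m0 <- sum(stw$support * stw$frequencies)
  m1 <- sum(shift_strata(stw, 0.123)$support * stw$frequencies)
  expect_equal(m1 - m0, 0.123, tolerance = 1e-12)
})

test_that("strata validation rejects malformed inputs", {
  expect_error(new_strata(c(3, 3), c(0.5, 0.5)), "increasing")
  expect_error(new_strata(c(3, 4), c(0.7, 0.7)), "sum to 1")
})
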