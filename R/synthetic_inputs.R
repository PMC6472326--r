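# Synthetic demographic, nutritional, biomarker, risk, land and cost inputs.

#' Generate a synthetic population state
#'
#' Counts by region x location x five-year age band x gender, plus vital
#' rates: fertility by female age band, background mortality by age and
#' gender (monotone over the oldest bands), and region/location net
#' migration summing to zero nationally.
#'
#' @param dims a [model_dims()] object.
#' @param seed integer seed.
#' @param total_population national total person count.
#' @return object of class `population_state`.
#' @export
generate_population <- function(dims = model_dims(), seed = 1L,
                                total_population = 2e7) {
  validate_dims(dims)
  with_seed(child_seed(seed, 11L), {
    nR <- dims$n_regions
    nL <- 2L
    nA <- 13L
    # stylized pyramid over the modelled bands (10-14 ... 70+)
    pyr <- exp(-0.06 * (seq_len(nA) - 1)) * stats::runif(nA, 0.95, 1.05)
    pyr <- pyr / sum(pyr)
    cell_w <- array(stats::rgamma(nR * nL, shape = 5), dim = c(nR, nL))
    # Bangkok-style single-location regions have no rural population
    for (r in seq_len(nR)) {
      locs <- dims$household_location[dims$household_region == dims$regions[r]]
      if (!"rural" %in% locs) cell_w[r, 1L] <- 0
      if (!"urban" %in% locs) cell_w[r, 2L] <- 0
    }
    cell_w <- cell_w / sum(cell_w)
    counts <- array(0, dim = c(nR, nL, nA, 2L),
                    dimnames = list(dims$regions, dims$locations,
                                    dims$age_groups, dims$genders))
    sexr <- c(male = 0.497, female = 0.503)
    for (r in seq_len(nR)) for (l in seq_len(nL)) {
      base <- total_population * cell_w[r, l] * pyr
      counts[r, l, , 1L] <- base * sexr[1L] * stats::runif(nA, 0.98, 1.02)
      counts[r, l, , 2L] <- base * sexr[2L] * stats::runif(nA, 0.98, 1.02)
    }
    counts[counts > 0 & counts < 1] <- 1  # strictly positive occupied cells

    fertility <- numeric(nA)
    names(fertility) <- dims$age_groups
    fert_bands <- which(dims$age_starts >= 15 & dims$age_starts <= 45)
    fertility[fert_bands] <- c(0.020, 0.080, 0.100, 0.070, 0.030, 0.010,
                               0.002) * stats::runif(7, 0.9, 1.1)

    mortality <- matrix(0, nA, 2L, dimnames = list(dims$age_groups,
                                                   dims$genders))
    base_m <- 5e-4 * exp(0.42 * (seq_len(nA) - 1))
    mortality[, 1L] <- pmin(cummax(base_m * 1.2 *
                                     stats::runif(nA, 0.95, 1.05)), 0.5)
    mortality[, 2L] <- pmin(cummax(base_m *
                                     stats::runif(nA, 0.95, 1.05)), 0.5)

    migration <- array(stats::rnorm(nR * nL, 0, 1e-3) *
                         apply(counts, c(1, 2), sum),
                       dim = c(nR, nL),
                       dimnames = list(dims$regions, dims$locations))
    occupied <- apply(counts, c(1, 2), sum) > 0
    migration[!occupied] <- 0
    migration[occupied] <- migration[occupied] - mean(migration[occupied])

    structure(list(dims = dims, counts = counts, fertility = fertility,
                   mortality = mortality, migration = migration,
                   reported_total = sum(counts),
                   person_years = 0),
              class = "population_state")
  })
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> total", format(round(sum(x$counts)), big.mark = ","),
      "persons in", length(x$dims$regions), "regions\n")
  invisible(x)
}

#' Generate a crop-to-crop land-use-change emission coefficient matrix
#'
#' Entry `[i, j]` is tonnes CO2-eq emitted per hectare converted from crop
#' `i` to crop `j`, computed as the difference of per-crop carbon stocks, so
#' the matrix is antisymmetric with a zero diagonal.  Oil palm carries the
#' largest stock, making conversion from annual crops into oil palm a net
#' sequestration (negative coefficient).
#'
#' @param dims a [model_dims()] object (needs >= 2 non-palm primary crops).
#' @param seed integer seed.
#' @return matrix of class `luc_matrix` with attribute `carbon_stocks`.
#' @export
generate_luc_matrix <- function(dims = model_dims(), seed = 1L) {
  validate_dims(dims)
  with_seed(child_seed(seed, 12L), {
    k <- length(dims$crops)
    cs <- stats::runif(k, 18, 26)                # annual crops: similar stocks
    cs[1L] <- stats::runif(1, 110, 140)          # oil palm standing stock
    names(cs) <- dims$crops
    m <- outer(cs, cs, `-`)
    dimnames(m) <- list(from = dims$crops, to = dims$crops)
    structure(m, class = c("luc_matrix", "matrix"), carbon_stocks = cs)
  })
}

# Household x commodity energy density (kcal per currency unit of real
# consumption) and fatty-acid energy fractions, scaled so benchmark intake
# is ~2100 kcal/person/day.
draw_nutrient_coefficients <- function(dims, bench, population) {
  com <- dims$commodities
  nC <- length(com)
  nH <- dims$n_households
  is_food <- com %in% dims$food_commodities
  rel <- numeric(nC)
  rel[com == dims$palm_oil] <- 8
  rel[com == dims$other_oils] <- 7
  rel[com %in% dims$crops & is_food] <- 4.5
  rel[is_food & rel == 0] <- 3
  ed <- matrix(0, nC, nH, dimnames = list(com, dims$households))
  hh_pop <- household_population(dims, population)
  for (h in seq_len(nH)) {
    r <- rel * stats::runif(nC, 0.9, 1.1)
    q0 <- bench$theta[, h] * bench$EH[h]
    raw <- sum(q0 * r) / (hh_pop[h] * 365)
    target <- 2100 * stats::runif(1, 0.95, 1.05)
    ed[, h] <- r * target / raw
  }
  frac <- function(base, jit = 0.02) {
    pmax(base + stats::rnorm(length(base), 0, jit), 0)
  }
  sfa <- mufa <- pufa <- matrix(0, nC, nH, dimnames = dimnames(ed))
  for (h in seq_len(nH)) {
    s <- m <- p <- numeric(nC)
    i <- com == dims$palm_oil
    s[i] <- frac(0.49); m[i] <- frac(0.37); p[i] <- frac(0.10)
    i <- com == dims$other_oils                  # soybean/sunflower blend
    s[i] <- frac(0.10); m[i] <- frac(0.25); p[i] <- frac(0.60)
    i <- com %in% dims$crops & is_food
    s[i] <- frac(rep(0.02, sum(i))); m[i] <- frac(rep(0.02, sum(i)))
    p[i] <- frac(rep(0.03, sum(i)))
    i <- is_food & !(com %in% c(dims$palm_oil, dims$other_oils, dims$crops))
    s[i] <- frac(rep(0.10, sum(i))); m[i] <- frac(rep(0.08, sum(i)))
    p[i] <- frac(rep(0.10, sum(i)))
    tot <- s + m + p
    over <- tot > 0.98
    if (any(over)) {
      s[over] <- s[over] * 0.98 / tot[over]
      m[over] <- m[over] * 0.98 / tot[over]
      p[over] <- p[over] * 0.98 / tot[over]
    }
    sfa[, h] <- s; mufa[, h] <- m; pufa[, h] <- p
  }
  structure(list(energy_density = ed, sfa = sfa, mufa = mufa, pufa = pufa),
            class = "nutrient_coefficients")
}

# Total:HDL cholesterol ratio distribution parameters: household-level means
# by age/gender plus location-level standard deviations used for the lookup
# table simulation.
draw_biomarker_distributions <- function(dims, population) {
  nA <- 13L
  mean_base <- array(0, dim = c(nA, 2L, 2L),
                     dimnames = list(dims$age_groups, dims$genders,
                                     dims$locations))
  sd_agl <- mean_base
  mids <- dims$age_starts + 2.5
  for (g in 1:2) for (l in 1:2) {
    shift <- (g == 1L) * 0.15 + (l == 2L) * 0.10
    mean_base[, g, l] <- pmin(pmax(3.55 + 0.022 * (mids - 12) + shift +
                                     stats::rnorm(nA, 0, 0.04), 2.5), 6.5)
    sd_agl[, g, l] <- stats::runif(nA, 0.60, 0.90)
  }
  hh_shift <- stats::rnorm(dims$n_households, 0, 0.05)
  names(hh_shift) <- dims$households
  structure(list(mean = mean_base, sd = sd_agl, household_shift = hh_shift,
                 dims = dims),
            class = "biomarker_distributions")
}

# Mean/sd pair for one household x age x gender cell.
biomarker_cell <- function(bio, household, age_idx, gender_idx) {
  loc <- bio$dims$household_location[household]
  l <- match(loc, bio$dims$locations)
  c(mean = unname(bio$mean[age_idx, gender_idx, l] +
                    bio$household_shift[household]),
    sd = unname(bio$sd[age_idx, gender_idx, l]))
}

# Monotone bounded risk functions per disease x age x gender x location:
# scaled logistic curves in the cholesterol ratio.
draw_risk_functions <- function(dims) {
  dn <- list(disease = c("mi", "stroke"), age = dims$age_groups,
             gender = dims$genders, location = dims$locations)
  dmn <- c(2L, 13L, 2L, 2L)
  cap_inc <- array(0, dmn, dn)
  cap_mort <- array(0, dmn, dn)
  mid <- array(stats::runif(prod(dmn), 4.8, 5.4), dmn, dn)
  slope <- array(stats::runif(prod(dmn), 1.0, 1.5), dmn, dn)
  agemult <- exp(0.45 * (seq_len(13L) - 13L))
  for (d in 1:2) for (g in 1:2) for (l in 1:2) {
    base <- if (d == 1L) 0.010 else 0.007
    gmult <- if (d == 1L) c(1.25, 0.8)[g] else c(1.1, 0.9)[g]
    lmult <- if (l == 2L) 1.1 else 1.0
    fatal <- if (d == 1L) 0.5 else 0.35
    cap_inc[d, , g, l] <- base * gmult * lmult * agemult *
      stats::runif(13L, 0.9, 1.1)
    cap_mort[d, , g, l] <- cap_inc[d, , g, l] * fatal *
      stats::runif(13L, 0.9, 1.1)
  }
  structure(list(cap_incidence = cap_inc, cap_mortality = cap_mort,
                 mid = mid, slope = slope, diseases = c("mi", "stroke"),
                 dims = dims),
            class = "risk_function_set")
}

#' Evaluate a synthetic risk function
#'
#' @param risks a `risk_function_set`.
#' @param type `"incidence"` or `"mortality"` (annual excess mortality).
#' @param disease `"mi"` or `"stroke"`.
#' @param age_idx,gender_idx,location_idx cell indices.
#' @param c_values cholesterol ratio values.
#' @return annual probabilities in \[0, 1\], non-decreasing in `c_values`.
#' @export
risk_rate <- function(risks, type, disease, age_idx, gender_idx,
                      location_idx, c_values) {
  d <- match(disease, risks$diseases)
  cap <- if (type == "incidence") {
    risks$cap_incidence[d, age_idx, gender_idx, location_idx]
  } else {
    risks$cap_mortality[d, age_idx, gender_idx, location_idx]
  }
  k <- risks$slope[d, age_idx, gender_idx, location_idx]
  m <- risks$mid[d, age_idx, gender_idx, location_idx]
  pmin(pmax(cap * stats::plogis(k * (c_values - m)), 0), 1)
}

# YLD weights, caregiver time, hospital unit costs, participation and
# retirement parameters.  Costs are in SAM currency units.
draw_cost_parameters <- function(dims) {
  structure(list(
    yld_weight = c(mi = 0.43, stroke = 0.32),
    duration_mi = 0.02,                          # acute episode, years
    duration_stroke = 5,                         # capped at horizon remainder
    caregiver_work_py = 0.10,                    # per stroke case
    caregiver_leisure_py = 0.15,
    hospital_cost = c(mi = 0.003, stroke = 0.005),
    worktime_loss_py = c(mi = 0.08, stroke = 0.45),
    participation = c(male = 0.78, female = 0.66),
    retirement_age = 65,
    skill_split = 0.35                           # skilled share of labour
  ), class = "health_cost_parameters")
}

# Hectares per unit of real crop output, anchored to a fixed synthetic
# cropland endowment allocated in proportion to benchmark land use.
draw_land_yields <- function(dims, bench, sh, total_cropland = 4e6) {
  land_val <- sh$phi["land", dims$crops] * bench$QA[dims$crops]
  ha0 <- total_cropland * land_val / sum(land_val)
  yields <- ha0 / bench$QA[dims$crops]
  list(yields = yields, hectares0 = ha0)
}

# Population-weighted initial biomarker strata per household: equal-frequency
# support points of the household's pooled normal distribution.
initial_strata <- function(dims, bio, population) {
  ns <- dims$strata_count
  qs <- stats::qnorm((seq_len(ns) - 0.5) / ns)
  out <- lapply(stats::setNames(dims$households, dims$households),
                function(h) {
    r <- match(dims$household_region[h], dims$regions)
    l <- match(dims$household_location[h], dims$locations)
    w <- population$counts[r, l, , ]             # age x gender
    mu <- sd2 <- 0
    wt <- w / sum(w)
    for (a in 1:13) for (g in 1:2) {
      cell <- biomarker_cell(bio, h, a, g)
      mu <- mu + wt[a, g] * cell["mean"]
    }
    for (a in 1:13) for (g in 1:2) {
      cell <- biomarker_cell(bio, h, a, g)
      sd2 <- sd2 + wt[a, g] * (cell["sd"]^2 + (cell["mean"] - mu)^2)
    }
    new_strata(support = as.numeric(mu) + sqrt(as.numeric(sd2)) * qs,
               frequencies = rep(1 / ns, ns))
  })
  out
}

# Total persons per household cell (its region x location).
household_population <- function(dims, population) {
  vapply(dims$households, function(h) {
    r <- match(dims$household_region[h], dims$regions)
    l <- match(dims$household_location[h], dims$locations)
    sum(population$counts[r, l, , ])
  }, numeric(1))
}
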