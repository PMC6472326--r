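# Cohort-component projection on five-year bands with an annual step, and
# labour-supply derivation from the working-age population.

#' Project the population one annual step
#'
#' Deaths are background mortality plus (optionally) CVD excess deaths by
#' region/location/age/gender; births apply fertility rates to female
#' bands and enter the first modelled band; ageing graduates one fifth of
#' each five-year band per year (the open-ended last band only receives);
#' net migration is distributed over cells in proportion to population.
#' The accounting identity `pop_next = pop + births - deaths + migration`
#' holds exactly per region x location.
#'
#' @param state a `population_state`.
#' @param excess_deaths optional array (region x location x age x gender)
#'   of additional deaths; capped at cell populations with a warning.
#' @param dt time step in years (the module is annual; `dt = 1`).
#' @return updated `population_state` with a `flows` attribute recording
#'   births, deaths and migration of the step.
#' @export
project_population <- function(state, excess_deaths = NULL, dt = 1) {
  stopifnot(inherits(state, "population_state"))
  if (dt != 1) stop("annual steps only (dt = 1)", call. = FALSE)
  dims <- state$dims
  counts <- state$counts
  nA <- 13L

  deaths <- counts * 0
  for (g in 1:2) {
    deaths[, , , g] <- sweep(counts[, , , g, drop = FALSE], 3L,
                             state$mortality[, g], `*`)
  }
  if (!is.null(excess_deaths)) {
    deaths <- deaths + excess_deaths
    over <- deaths > counts
    if (any(over)) {
      warning(sum(over), " cells had excess deaths exceeding population; ",
              "capped", call. = FALSE)
      deaths[over] <- counts[over]
    }
  }
  surv <- counts - deaths

  # births from female fertility, entering the first band
  births_rl <- apply(sweep(surv[, , , 2L, drop = FALSE], 3L,
                           state$fertility, `*`), c(1L, 2L), sum)
  sexr <- c(0.512, 0.488)

  aged <- surv
  move <- surv / 5
  aged <- aged - move
  aged[, , 2:nA, ] <- aged[, , 2:nA, ] + move[, , 1:(nA - 1L), ]
  aged[, , nA, ] <- aged[, , nA, ] + move[, , nA, ]   # 70+ retains its own
  for (g in 1:2) aged[, , 1L, g] <- aged[, , 1L, g] + births_rl * sexr[g]

  cell_pop <- apply(aged, c(1L, 2L), sum)
  mig <- aged * 0
  for (r in seq_len(dim(aged)[1L])) for (l in 1:2) {
    if (cell_pop[r, l] > 0) {
      mig[r, l, , ] <- state$migration[r, l] * aged[r, l, , ] / cell_pop[r, l]
    }
  }
  nxt <- pmax(aged + mig, 0)

  out <- state
  out$counts <- nxt
  out$reported_total <- sum(nxt)
  out$person_years <- state$person_years + sum(nxt)
  attr(out, "flows") <- list(births = sum(births_rl), deaths = sum(deaths),
                             migration = sum(mig))
  out
}

#' Derive labour supply from the population state
#'
#' Working-age person-years (ages 15 up to the retirement age, with
#' fractional inclusion of the band containing the retirement age) times
#' workforce participation rates, split into skilled and unskilled by a
#' fixed ratio, minus patient and caregiver worktime losses.
#'
#' @param state a `population_state`.
#' @param params a `health_cost_parameters` object (participation rates,
#'   retirement age, skill split).
#' @param worktime_losses total person-years lost to patient and caregiver
#'   time, subtracted proportionally from both skill classes.
#' @param allow_retirement_override allow retirement ages outside the
#'   supported 59--69 grid.
#' @return list with `skilled`, `unskilled`, `working_age`, `participation`.
#' @export
derive_labour_supply <- function(state, params, worktime_losses = 0,
                                 allow_retirement_override = FALSE) {
  dims <- state$dims
  ra <- params$retirement_age
  if ((ra < 59 || ra > 69) && !allow_retirement_override) {
    stop("retirement age ", ra, " outside the supported [59, 69] grid; ",
         "set `allow_retirement_override = TRUE` to force", call. = FALSE)
  }
  w <- working_weights(dims, ra)
  by_gender <- vapply(1:2, function(g) {
    sum(sweep(state$counts[, , , g, drop = FALSE], 3L, w, `*`))
  }, numeric(1))
  working_age <- sum(by_gender)
  lab <- sum(by_gender * params$participation) - worktime_losses
  lab <- max(lab, 0)
  list(skilled = lab * params$skill_split,
       unskilled = lab * (1 - params$skill_split),
       working_age = working_age,
       participation = sum(by_gender * params$participation) /
         max(working_age, 1e-12))
}
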