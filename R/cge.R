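# Within-period general equilibrium and recursive dynamics.
#
# Functional forms: Leontief intermediates over CES value added
# (labour/capital/land); Armington CES between imports and domestic
# varieties; CET between exports and domestic sales; AIDS household demand;
# small open economy with fixed world prices and a flexible real exchange
# rate; CPI numeraire.  The within-period system is solved by a damped
# Newton method on a square residual vector in log prices/quantities.

#' CGE configuration
#'
#' @param sigma_va CES substitution elasticity in value added.
#' @param sigma_q Armington elasticity between imports and domestic goods.
#' @param sigma_t CET transformation elasticity exports vs domestic sales.
#' @param delta annual capital depreciation rate.
#' @param capital_rate benchmark capital service flow per unit of stock.
#' @param solver_tol Newton convergence tolerance on scaled residuals.
#' @param feedback_tol relative tolerance of the within-period health
#'   feedback fixed point.
#' @param feedback_max_sweeps maximum health feedback sweeps per period.
#' @return list of class `cge_config`.
#' @export
cge_config <- function(sigma_va = 0.8, sigma_q = 2, sigma_t = 2,
                       delta = 0.05, capital_rate = 0.1,
                       solver_tol = 1e-10, feedback_tol = 1e-7,
                       feedback_max_sweeps = 50L) {
  structure(list(sigma_va = sigma_va, sigma_q = sigma_q, sigma_t = sigma_t,
                 delta = delta, capital_rate = capital_rate,
                 solver_tol = solver_tol, feedback_tol = feedback_tol,
                 feedback_max_sweeps = feedback_max_sweeps),
            class = "cge_config")
}

# --- CES / CET primitives (share-form calibration at unit prices) --------

ces_calibrate <- function(X0, sigma) {
  rho <- (sigma - 1) / sigma
  a <- numeric(length(X0))
  pos <- X0 > 0
  a[pos] <- X0[pos]^(1 - rho)
  a <- a / sum(a)
  Q0 <- sum(X0)
  A <- Q0 / sum(a[pos] * X0[pos]^rho)^(1 / rho)
  list(a = a, A = A, sigma = sigma)
}

ces_cost <- function(p, cal) {
  s <- cal$sigma
  pos <- cal$a > 0
  (sum(cal$a[pos]^s * p[pos]^(1 - s)))^(1 / (1 - s)) / cal$A
}

ces_demand <- function(Q, p, cal, cost) {
  s <- cal$sigma
  Q * cal$a^s * ifelse(cal$a > 0, p^(-s), 0) * cost^s * cal$A^(s - 1)
}

cet_calibrate <- function(X0, sigma_t) {
  rho <- 1 + 1 / sigma_t
  pos <- X0 > 0
  b <- numeric(length(X0))
  b[pos] <- X0[pos]^(1 - rho)
  b <- b / sum(b)
  Q0 <- sum(X0)
  B <- Q0 / sum(b[pos] * X0[pos]^rho)^(1 / rho)
  list(b = b, B = B, st = sigma_t)
}

cet_revenue <- function(p, cal) {
  st <- cal$st
  pos <- cal$b > 0
  (sum(cal$b[pos]^(-st) * p[pos]^(1 + st)))^(1 / (1 + st)) / cal$B
}

cet_supply <- function(Q, p, cal, rev) {
  ifelse(cal$b > 0, (Q / cal$B) * (p / (cal$b * rev * cal$B))^cal$st, 0)
}

# --- Calibration ----------------------------------------------------------

#' Calibrate economy parameters from a synthetic truth
#'
#' Extracts Leontief intermediate coefficients, CES value-added share
#' parameters, Armington/CET trade parameters, tax and savings rates,
#' factor endowments, consumer-price-index weights and demand-system
#' parameters from the balanced SAM so that the zero-shock model
#' replicates the benchmark exactly.
#'
#' @param truth a `synthetic_truth`.
#' @param config a [cge_config()].
#' @param aids optional named list of `aids_parameters` per household
#'   (defaults to the truth's own parameters).
#' @return object of class `economy_parameters`.
#' @export
calibrate_economy <- function(truth, config = cge_config(), aids = NULL) {
  dims <- truth$dims
  b <- truth$benchmark
  sh <- truth$shares
  nC <- dims$n_commodities
  nF <- length(dims$factors)
  com <- dims$commodities

  QF0 <- sweep(sh$phi, 2L, b$QA, `*`)            # factor value = quantity
  ces_va <- lapply(seq_len(nC), function(a) ces_calibrate(QF0[, a],
                                                          config$sigma_va))
  iva <- colSums(QF0) / b$QA
  QD0 <- b$QA - b$E
  arm <- vector("list", nC)
  cet <- vector("list", nC)
  for (c_ in seq_len(nC)) {
    if (b$M[c_] > 1e-12) {
      arm[[c_]] <- ces_calibrate(c(QD0[c_], b$M[c_]), config$sigma_q)
    }
    if (b$E[c_] > 1e-12) {
      cet[[c_]] <- cet_calibrate(c(QD0[c_], b$E[c_]), config$sigma_t)
    }
  }
  EH0 <- b$EH
  cons0 <- sweep(b$theta, 2L, EH0, `*`)
  cwts <- rowSums(cons0) / sum(cons0)
  absorption0 <- sum(EH0) + sum(b$INV) + sum(b$G0)

  structure(list(
    dims = dims, config = config,
    io = sh$io, iva = iva, ces_va = ces_va, arm = arm, cet = cet,
    aids = aids %||% truth$aids_parameters,
    td0 = stats::setNames(sh$td, dims$households),
    mps = stats::setNames(sh$mps, dims$households),
    omega = sh$omega,
    cwts = cwts,
    pwm = rep(1, nC), pwe = rep(1, nC), tm = rep(0, nC),
    g0 = b$G0, gshare0 = sum(b$G0) / absorption0,
    inv0 = b$INV, fsav0 = b$FSAV,
    FS0 = stats::setNames(b$YF, dims$factors),
    QA0 = b$QA, QQ0 = b$QQ, EH0 = EH0, gdp0 = b$gdp,
    drop_market = which.max(b$QA)
  ), class = "economy_parameters")
}

#' Initial dynamic state at the benchmark
#'
#' @param params an `economy_parameters`.
#' @return object of class `dynamic_state` holding factor endowments,
#'   capital stock, productivity and price-level shifters.
#' @export
initial_state <- function(params) {
  cfg <- params$config
  structure(list(
    FS = params$FS0,
    capital = params$FS0[["capital"]] / cfg$capital_rate,
    tfp = 1, pfac = 1, fsav = params$fsav0,
    period = 1L
  ), class = "dynamic_state")
}

# --- Closures -------------------------------------------------------------

#' Closure specification for the within-period solve
#'
#' @param type one of `"baseline"` (government consumption scales to keep a
#'   fixed consumption-to-absorption ratio), `"policy"` (iso-government:
#'   real government consumption fixed at the counterfactual path, sales
#'   tax revenue recycled through uniform additive direct-tax reductions),
#'   `"iso_budget"`, `"iso_real"`, `"iso_both"` (compensating lump-sum
#'   transfer variants).
#' @param ts sales tax rate vector by commodity.
#' @param QG real government consumption vector (policy closures).
#' @param sg_target government savings target (policy / iso_both).
#' @param eh_target,realcons_target per-household nominal budget / real
#'   consumption targets for the iso closures.
#' @param trh_fixed fixed per-household lump-sum transfers (e.g. the
#'   negative of hospital-cost deltas when households pay them).
#' @return list of class `closure_spec`.
#' @export
closure_spec <- function(type = "baseline", ts = NULL, QG = NULL,
                         sg_target = NULL, eh_target = NULL,
                         realcons_target = NULL, trh_fixed = NULL) {
  structure(list(type = type, ts = ts, QG = QG, sg_target = sg_target,
                 eh_target = eh_target, realcons_target = realcons_target,
                 trh_fixed = trh_fixed),
            class = "closure_spec")
}

n_extra <- function(closure, nH) {
  switch(closure$type,
         baseline = 1L, policy = 1L,
         iso_budget = nH, iso_real = nH, iso_both = nH + 1L,
         stop("unknown closure type ", closure$type, call. = FALSE))
}

# --- Within-period solve --------------------------------------------------

# Compute the full flow table implied by an unknown vector.
eval_economy <- function(x, params, state, closure) {
  dims <- params$dims
  nC <- dims$n_commodities
  nF <- length(dims$factors)
  nH <- dims$n_households
  pdd <- exp(x[seq_len(nC)])
  qa <- exp(x[nC + seq_len(nC)])
  wf <- exp(x[2 * nC + seq_len(nF)])
  exr <- exp(x[2 * nC + nF + 1L])
  extra <- x[(2 * nC + nF + 2L):length(x)]

  ts <- closure$ts %||% rep(0, nC)
  pm <- params$pwm * (1 + params$tm) * exr
  pe <- params$pwe * exr

  pq <- pdd
  kd <- km <- rep(0, nC)
  for (c_ in seq_len(nC)) {
    if (!is.null(params$arm[[c_]])) {
      cal <- params$arm[[c_]]
      cost <- ces_cost(c(pdd[c_], pm[c_]), cal)
      pq[c_] <- cost
      dem <- ces_demand(1, c(pdd[c_], pm[c_]), cal, cost)
      kd[c_] <- dem[1L]; km[c_] <- dem[2L]
    } else {
      kd[c_] <- 1
    }
  }
  # Hicks-neutral productivity scales the CES value-added scale parameter;
  # unit cost divides by tfp and factor demands shrink proportionally.
  base_cost <- vapply(seq_len(nC), function(a) ces_cost(wf, params$ces_va[[a]]),
                      numeric(1))
  pva <- base_cost / state$tfp
  unit_cost <- params$iva * pva + as.numeric(crossprod(params$io, pq))
  rev <- pdd
  qd_sup <- qa
  qe <- rep(0, nC)
  for (c_ in seq_len(nC)) {
    if (!is.null(params$cet[[c_]])) {
      cal <- params$cet[[c_]]
      r <- cet_revenue(c(pdd[c_], pe[c_]), cal)
      rev[c_] <- r
      s <- cet_supply(qa[c_], c(pdd[c_], pe[c_]), cal, r)
      qd_sup[c_] <- s[1L]; qe[c_] <- s[2L]
    }
  }
  qva <- params$iva * qa
  qf <- matrix(0, nF, nC)
  for (a in seq_len(nC)) {
    qf[, a] <- ces_demand(qva[a], wf, params$ces_va[[a]], base_cost[a]) /
      state$tfp
  }

  pc <- pq * (1 + ts)
  YF <- wf * state$FS
  YH <- as.numeric(params$omega %*% YF)
  dtd <- 0
  TRH <- closure$trh_fixed %||% rep(0, nH)
  if (closure$type == "policy") dtd <- extra[1L]
  if (closure$type %in% c("iso_budget", "iso_real")) {
    TRH <- TRH + extra[seq_len(nH)]
  }
  if (closure$type == "iso_both") {
    TRH <- TRH + extra[seq_len(nH)]
    dtd <- extra[nH + 1L]
  }
  YD <- YH * (1 - params$td0 + dtd) + TRH
  EH <- (1 - params$mps) * YD
  SAV <- params$mps * YD
  w_sh <- matrix(0, nC, nH)
  for (h in seq_len(nH)) {
    w_sh[, h] <- aids_shares(params$aids[[h]], pc, EH[h])
  }
  qh <- sweep(w_sh, 2L, EH, `*`) / pc
  cons_tot <- rowSums(qh)

  QG <- if (closure$type == "baseline") params$g0 * extra[1L] else closure$QG
  int_dem <- as.numeric(params$io %*% qa)
  gval <- sum(pq * QG)
  dtax_tot <- sum((params$td0 - dtd) * YH)
  sales_rev <- sum(ts * pq * cons_tot)
  inv_cost <- sum(pq * params$inv0)
  # tariffs make total savings weakly self-referential through investment
  # demand; resolve the scalar linear fixed point analytically
  d0 <- int_dem + cons_tot + QG
  tar_unit <- params$tm * params$pwm * exr
  tariff0 <- sum(tar_unit * km * d0)
  tar_coef <- sum(tar_unit * km * params$inv0) / inv_cost
  sg_base <- dtax_tot + sales_rev + tariff0 - gval - sum(TRH)
  S <- (sum(SAV) + sg_base + state$fsav * exr) / (1 - tar_coef)
  qinv <- params$inv0 * (S / inv_cost)
  qq <- d0 + qinv
  qm <- km * qq
  qd_dem <- kd * qq
  tariff <- tariff0 + tar_coef * S
  SG <- dtax_tot + sales_rev + tariff - gval - sum(TRH)

  cpi <- sum(params$cwts * pc)
  gdp_real <- sum(qh) + sum(qinv) + sum(QG) + sum(qe) - sum(qm)
  gdp_nom <- sum(EH) + sum(pq * qinv) + gval + sum(pe * qe) -
    sum(params$pwm * exr * qm)

  list(pdd = pdd, qa = qa, wf = wf, exr = exr, pq = pq, pc = pc, pm = pm,
       pe = pe, pva = pva, rev = rev, unit_cost = unit_cost,
       qd_sup = qd_sup, qd_dem = qd_dem, qe = qe, qm = qm, qq = qq,
       qf = qf, qh = qh, qinv = qinv, QG = QG, EH = EH, SAV = SAV,
       YH = YH, YF = YF, dtd = dtd, TRH = TRH, SG = SG, S = S,
       dtax = (params$td0 - dtd) * YH, sales_rev = sales_rev,
       tariff = tariff, cpi = cpi, gdp_real = gdp_real, gdp_nom = gdp_nom,
       int_dem = int_dem, gval = gval, w_sh = w_sh, fsav = state$fsav)
}

residuals_economy <- function(x, params, state, closure) {
  e <- eval_economy(x, params, state, closure)
  dims <- params$dims
  nC <- dims$n_commodities
  nH <- dims$n_households
  scale_p <- state$pfac
  drop <- params$drop_market
  keep <- setdiff(seq_len(nC), drop)
  f_profit <- (e$rev - e$unit_cost) / scale_p
  f_market <- (e$qd_sup - e$qd_dem)[keep] / params$QA0[keep]
  f_factor <- (rowSums(e$qf) - state$FS) / params$FS0
  f_ext <- (sum(params$pwm * e$qm) - sum(params$pwe * e$qe) - state$fsav) /
    params$gdp0
  f_num <- e$cpi / scale_p - 1
  f_clos <- switch(closure$type,
    baseline = {
      absorb <- sum(e$EH) + sum(e$pq * e$qinv) + e$gval
      (e$gval - params$gshare0 * absorb) / params$gdp0
    },
    policy = (e$SG - closure$sg_target) / params$gdp0,
    iso_budget = (e$EH - closure$eh_target) / params$EH0,
    iso_real = (colSums(e$qh) - closure$realcons_target) / params$EH0,
    iso_both = c((colSums(e$qh) - closure$realcons_target) / params$EH0,
                 (e$SG - closure$sg_target) / params$gdp0)
  )
  c(f_profit, f_market, f_factor, f_ext, f_num, f_clos)
}

#' Solve the within-period general equilibrium
#'
#' Solves the square system of zero-profit, market-clearing, external
#' balance, numeraire and closure conditions by damped Newton iteration.
#' One domestic commodity market is dropped (Walras's law) and its excess
#' demand value is reported as the Walras residual.
#'
#' @param params an `economy_parameters`.
#' @param state a `dynamic_state`.
#' @param closure a [closure_spec()].
#' @param x0 optional warm-start unknown vector (from a previous solve).
#' @return object of class `equilibrium`; includes `walras_residual`
#'   relative to nominal GDP and the solved unknown vector `x`.
#' @export
solve_equilibrium <- function(params, state, closure = closure_spec(),
                              x0 = NULL) {
  dims <- params$dims
  nC <- dims$n_commodities
  nF <- length(dims$factors)
  nH <- dims$n_households
  nx <- 2L * nC + nF + 1L + n_extra(closure, nH)
  if (is.null(x0)) {
    lp <- log(state$pfac)
    x0 <- c(rep(lp, nC), log(params$QA0), rep(lp, nF), lp,
            rep(0, n_extra(closure, nH)))
    if (closure$type == "baseline") x0[nx] <- 1
  }
  sol <- newton_solve(function(x) residuals_economy(x, params, state,
                                                    closure),
                      x0, tol = params$config$solver_tol, maxit = 80L)
  if (!sol$converged) {
    stop("equilibrium solver failed to converge; max residual ",
         signif(max(abs(sol$fval)), 4), call. = FALSE)
  }
  e <- eval_economy(sol$x, params, state, closure)
  drop <- params$drop_market
  walras <- e$pdd[drop] * (e$qd_sup[drop] - e$qd_dem[drop]) / e$gdp_nom
  dimnames(e$qh) <- list(dims$commodities, dims$households)
  names(e$pdd) <- names(e$pq) <- names(e$pc) <- names(e$qa) <-
    names(e$qq) <- names(e$qe) <- names(e$qm) <- names(e$qinv) <-
    names(e$QG) <- dims$commodities
  names(e$wf) <- dims$factors
  dimnames(e$qf) <- list(dims$factors, dims$commodities)
  names(e$EH) <- names(e$YH) <- names(e$SAV) <- dims$households
  structure(c(e, list(walras_residual = walras, x = sol$x,
                      closure = closure, period = state$period)),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("<equilibrium> period", x$period, "GDP(real)", signif(x$gdp_real, 6),
      "CPI", signif(x$cpi, 6), "Walras", signif(x$walras_residual, 3), "\n")
  invisible(x)
}

#' Income-expenditure audit of a solved equilibrium
#'
#' @param eq an `equilibrium`.
#' @param params the `economy_parameters` used to solve it.
#' @return named vector of relative account closure errors (households,
#'   government, savings-investment, rest of world, activities,
#'   commodities).
#' @export
audit_equilibrium <- function(eq, params) {
  gdp <- abs(eq$gdp_nom)
  hh <- max(abs(eq$YH * (1 - params$td0 + eq$dtd) + eq$TRH -
                  (colSums(eq$qh * eq$pc) + eq$SAV)))
  gov <- abs(sum(eq$dtax) + eq$sales_rev + eq$tariff -
               (sum(eq$pq * eq$QG) + sum(eq$TRH) + eq$SG))
  si <- abs(sum(eq$SAV) + eq$SG + eq$fsav * eq$exr - sum(eq$pq * eq$qinv))
  row_ <- abs(sum(params$pwm * eq$qm) - sum(params$pwe * eq$qe) - eq$fsav) *
    eq$exr
  act <- max(abs(eq$rev * eq$qa - (eq$unit_cost * eq$qa)))
  comm <- max(abs(eq$pq * eq$qq - (eq$pdd * eq$qd_dem + eq$pm * eq$qm)))
  c(households = hh, government = gov, savings_investment = si,
    rest_of_world = row_, activities = act, commodities = comm) / gdp
}

# --- Dynamics -------------------------------------------------------------

#' Advance the dynamic state one period
#'
#' Standard capital accumulation `K' = (1 - delta) K + real investment`;
#' labour endowments are rebuilt from the working-age population times
#' participation and the fixed skill split, minus patient and caregiver
#' worktime losses (person-years, converted at the benchmark
#' persons-to-endowment ratios).
#'
#' @param state a `dynamic_state`.
#' @param eq the solved `equilibrium` of the current period.
#' @param params an `economy_parameters`.
#' @param labour list with `skilled` and `unskilled` person-years for the
#'   next period (already net of worktime losses), as returned by
#'   [derive_labour_supply()].
#' @param labour_conv benchmark endowment units per person-year (named
#'   `skilled`, `unskilled`).
#' @return updated `dynamic_state` for the next period.
#' @export
step_dynamics <- function(state, eq, params, labour, labour_conv) {
  cfg <- params$config
  inv_real <- sum(eq$qinv)
  K <- (1 - cfg$delta) * state$capital + inv_real
  if (K <= 0) {
    stop("capital stock would become non-positive (delta = ", cfg$delta,
         ", investment = ", signif(inv_real, 4), ")", call. = FALSE)
  }
  FS <- state$FS
  FS[["capital"]] <- cfg$capital_rate * K
  FS[["labour_skilled"]] <- labour$skilled * labour_conv[["skilled"]]
  FS[["labour_unskilled"]] <- labour$unskilled * labour_conv[["unskilled"]]
  state$FS <- FS
  state$capital <- K
  state$period <- state$period + 1L
  state
}
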