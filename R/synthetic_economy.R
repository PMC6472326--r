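# Synthetic calibration inputs with known ground truth.
#
# The generator builds a fully consistent micro-economy from seeded share
# parameters and solves the implied linear flow system, so the resulting
# social accounting matrix (SAM) is balanced by construction.  All other
# calibration inputs (demand-system parameters, nutrient coefficients,
# biomarker distributions, risk functions, population, land-use-change
# coefficients, cost parameters) are generated jointly so that every module
# can be tested against a recoverable truth.

sam_account_names <- function(dims) {
  list(
    com = paste0("com_", dims$commodities),
    act = paste0("act_", dims$commodities),
    fac = dims$factors,
    hh = dims$households,
    other = c("gov", "si", "row")
  )
}

# Draw the structural share parameters of the synthetic economy.
draw_economy_shares <- function(dims) {
  nC <- dims$n_commodities
  nH <- dims$n_households
  nF <- length(dims$factors)
  com <- dims$commodities
  is_crop <- com %in% dims$crops
  is_food <- com %in% dims$food_commodities
  is_health <- com == dims$health_commodity
  is_palm <- com == dims$palm_oil
  is_oils <- com == dims$other_oils

  # intermediate input intensity per activity; the edible-oil chains are
  # anchored to their feedstock crops (palm oil refines the oil-palm crop,
  # other oils crush the annual oilseed/other crops)
  int_share <- ifelse(is_crop, stats::runif(nC, 0.15, 0.30),
                      stats::runif(nC, 0.25, 0.45))
  int_share[is_palm | is_oils] <- stats::runif(sum(is_palm | is_oils),
                                               0.45, 0.60)
  io_w <- matrix(0, nC, nC, dimnames = list(com, com))
  food_proc0 <- is_food & !is_palm & !is_oils & !is_crop
  for (a in seq_len(nC)) {
    alpha <- rep(0.8, nC)
    # primary crops feed the food chains only (structural zeros elsewhere)
    alpha[is_crop] <- 0
    if (is_crop[a]) alpha[a] <- 0.4              # own seed/planting input
    if (is_palm[a]) alpha[com == dims$crops[1L]] <- 40
    if (is_oils[a]) alpha[com %in% dims$crops[-1L]] <- 15
    if (food_proc0[a]) alpha[is_crop & com != dims$crops[1L]] <- 2
    io_w[, a] <- rdirichlet1(alpha)
  }
  io <- sweep(io_w, 2L, int_share, `*`)          # value per unit output

  # factor value shares per activity (columns sum to value-added share)
  phi <- matrix(0, nF, nC, dimnames = list(dims$factors, com))
  for (a in seq_len(nC)) {
    va <- 1 - int_share[a]
    if (is_crop[a]) {
      # oil palm is the land-intensive plantation crop
      alpha_land <- if (com[a] == dims$crops[1L]) c(2, 0.8, 1.5, 6) else
        c(3, 1, 2, 2.2)                          # lu, ls, cap, land
      s <- rdirichlet1(alpha_land)
    } else {
      s <- c(rdirichlet1(c(3, 2, 3)), 0)
    }
    phi[, a] <- va * s
  }

  # factor income distribution to households: land tilted to rural areas
  omega <- matrix(0, nH, nF, dimnames = list(dims$households, dims$factors))
  rural <- dims$household_location == "rural"
  for (f in seq_len(nF)) {
    alpha <- rep(3, nH)
    if (dims$factors[f] == "land") alpha <- ifelse(rural, 6, 1)
    if (dims$factors[f] == "labour_skilled") alpha <- ifelse(rural, 2, 4)
    omega[, f] <- rdirichlet1(alpha)
  }

  td <- stats::runif(nH, 0.08, 0.15)             # direct tax rates
  mps <- stats::runif(nH, 0.10, 0.20)            # marginal propensity to save

  # household budget shares with a realistic palm-cooking-oil weight
  theta <- matrix(0, nC, nH, dimnames = list(com, dims$households))
  for (h in seq_len(nH)) {
    base <- numeric(nC)
    palm_target <- if (rural[h]) 0.010 else 0.006
    base[is_palm] <- palm_target
    base[is_oils] <- 0.011
    # households buy food crops, not the oil-palm fruit itself
    base[is_crop] <- 0.05 / max(sum(is_crop) - 1L, 1L)
    base[com == dims$crops[1L]] <- 0.002
    other_food <- is_food & !is_palm & !is_oils & !is_crop
    if (any(other_food)) base[other_food] <- 0.24 / sum(other_food)
    base[is_health] <- 0.03
    nonfood <- !is_food & !is_health
    base[nonfood] <- (1 - sum(base)) / sum(nonfood)
    jit <- exp(stats::rnorm(nC, 0, 0.12))
    theta[, h] <- base * jit / sum(base * jit)
  }

  # trade intensities (shares of output exported / of absorption imported)
  es <- numeric(nC)
  es[is_crop] <- stats::runif(sum(is_crop), 0.08, 0.18)
  # oil-palm fruit must be processed close to harvest: no direct exports
  es[com == dims$crops[1L]] <- 0
  es[is_palm] <- stats::runif(1, 0.06, 0.12)
  es[is_oils] <- stats::runif(1, 0.03, 0.08)
  nonfood <- !is_food & !is_health
  es[nonfood] <- stats::runif(sum(nonfood), 0.10, 0.30)
  food_proc <- is_food & !is_palm & !is_oils & !is_crop
  es[food_proc] <- stats::runif(sum(food_proc), 0.05, 0.12)
  es[is_health] <- 0

  ms <- numeric(nC)
  ms[nonfood] <- stats::runif(sum(nonfood), 0.10, 0.25)
  ms[is_oils] <- stats::runif(1, 0.10, 0.18)
  ms[is_palm] <- stats::runif(1, 0.02, 0.06)
  ms[is_crop] <- stats::runif(sum(is_crop), 0.02, 0.08)
  ms[food_proc] <- stats::runif(sum(food_proc), 0.05, 0.12)
  ms[is_health] <- 0

  # government and investment demand composition
  gw <- numeric(nC)
  gw[is_health] <- 0.30
  gw[nonfood] <- 0.65 * rdirichlet1(rep(2, sum(nonfood)))
  gw[food_proc] <- 0.05 * rdirichlet1(rep(2, sum(food_proc)))
  gw <- gw / sum(gw)

  iw <- numeric(nC)
  iw[nonfood] <- rdirichlet1(rep(2, sum(nonfood)) +
                               4 * grepl("manufacturing", com[nonfood]))
  iw <- iw / sum(iw)

  list(io = io, phi = phi, omega = omega, td = td, mps = mps, theta = theta,
       es = es, ms = ms, gov_w = gw, inv_w = iw,
       fsav_ratio = stats::runif(1, 0.05, 0.15))
}

# Solve the linear flow system implied by the share parameters and assemble
# the balanced SAM plus the benchmark quantity tables.
build_balanced_sam <- function(dims, sh, gov_scale = 150) {
  nC <- dims$n_commodities
  nH <- dims$n_households
  eh_rate <- (1 - sh$mps) * (1 - sh$td)          # EH per unit household income
  sv_rate <- sh$mps * (1 - sh$td)
  hh_inc <- sh$omega %*% sh$phi                  # nH x nA: income per unit QA
  mratio <- sh$ms / (1 - sh$ms)                  # imports per unit dom. sales

  g_total <- gov_scale
  income_target <- 800                           # scale anchor (currency)
  QA <- rep(1, nC)
  for (pass in 1:8) {
    # anchor foreign savings at a small positive share of exports so total
    # savings (and hence investment) stay positive
    E_try <- sh$es * QA
    M_try <- mratio * (1 - sh$es) * QA
    if (sum(M_try) > 0 && sum(E_try) > 0) {
      mratio <- mratio * (1 + sh$fsav_ratio) * sum(E_try) / sum(M_try)
    }
    supply_coef <- (1 - sh$es) * (1 + mratio)    # QQ per unit QA
    fsav_coef <- mratio * (1 - sh$es) - sh$es
    G0 <- sh$gov_w * g_total
    # demand linear in QA: intermediates + consumption + investment
    cons_mat <- sh$theta %*% (eh_rate * hh_inc)  # nC x nA
    savrow <- colSums((sv_rate + sh$td) * hh_inc) + fsav_coef
    A <- diag(supply_coef, nC) - sh$io - cons_mat - outer(sh$inv_w, savrow)
    rhs <- G0 - sh$inv_w * sum(G0)
    # budget identities make one commodity equation redundant for any QA;
    # replace it with a scale normalization on total household income
    A[nC, ] <- colSums(hh_inc)
    rhs[nC] <- income_target
    QA <- as.numeric(solve(A, rhs))
    YH <- as.numeric(hh_inc %*% QA)
    g_total <- 0.8 * sum(sh$td * YH)             # keep government savings > 0
  }
  if (any(QA <= 0)) stop("synthetic economy infeasible: non-positive output",
                         call. = FALSE)
  names(QA) <- dims$commodities

  YF <- as.numeric(sh$phi %*% QA)
  names(YF) <- dims$factors
  YH <- as.numeric(hh_inc %*% QA)
  names(YH) <- dims$households
  DTAX <- sh$td * YH
  SAV <- sv_rate * YH
  EH <- eh_rate * YH
  E <- sh$es * QA
  M <- mratio * (1 - sh$es) * QA
  FSAV <- sum(M) - sum(E)
  GSAV <- sum(DTAX) - sum(G0)
  TOTSAV <- sum(SAV) + GSAV + FSAV
  INV <- sh$inv_w * TOTSAV
  if (TOTSAV <= 0 || GSAV <= 0 || FSAV <= 0) {
    stop("synthetic economy infeasible: non-positive savings aggregate",
         call. = FALSE)
  }
  CONS <- sh$theta %*% diag(EH, nH)
  QQ <- supply_coef * QA

  acc <- sam_account_names(dims)
  all_acc <- c(acc$com, acc$act, acc$fac, acc$hh, acc$other)
  sam <- matrix(0, length(all_acc), length(all_acc),
                dimnames = list(all_acc, all_acc))
  sam[acc$com, acc$act] <- sweep(sh$io, 2L, QA, `*`)
  sam[cbind(acc$act, acc$com)] <- QA
  sam[acc$fac, acc$act] <- sweep(sh$phi, 2L, QA, `*`)
  sam[acc$hh, acc$fac] <- sweep(sh$omega, 2L, YF, `*`)
  sam[acc$com, acc$hh] <- CONS
  sam["gov", acc$hh] <- DTAX
  sam["si", acc$hh] <- SAV
  sam[acc$com, "gov"] <- G0
  sam["si", "gov"] <- GSAV
  sam[acc$com, "si"] <- INV
  sam[acc$com, "row"] <- E
  sam["row", acc$com] <- M
  if (FSAV >= 0) sam["si", "row"] <- FSAV else sam["row", "si"] <- -FSAV

  gap <- max(abs(rowSums(sam) - colSums(sam))) / max(rowSums(sam))
  if (gap > 1e-9) stop("internal error: synthetic SAM unbalanced", call. = FALSE)

  bench <- list(QA = QA, QQ = QQ, YF = YF, YH = YH, EH = EH, DTAX = DTAX,
                SAV = SAV, E = E, M = M, G0 = G0, INV = INV, GSAV = GSAV,
                FSAV = FSAV, TOTSAV = TOTSAV, theta = sh$theta,
                gdp = sum(EH) + sum(INV) + sum(G0) + sum(E) - sum(M))
  list(sam = sam, bench = bench)
}

# Ground-truth AIDS parameters for one household, built to satisfy the full
# set of regularity constraints (adding-up, homogeneity, symmetry).  Palm
# cooking oil and other edible oils are strong gross substitutes, the
# substitution channel that shifts diets towards PUFA-dense oils when palm
# oil is taxed.
draw_aids_truth <- function(dims, w0, eh0) {
  nC <- length(w0)
  ip <- which(dims$commodities == dims$palm_oil)
  io_ <- which(dims$commodities == dims$other_oils)
  eta <- stats::runif(nC, 0.90, 1.30)
  eta[ip] <- stats::runif(1, 1.05, 1.20)
  eta <- eta + (1 - sum(w0 * eta))               # Engel aggregation
  beta <- w0 * (eta - 1)

  eps_own <- stats::runif(nC, -1.10, -0.85)
  eps_own[ip] <- stats::runif(1, -1.00, -0.90)
  g_diag <- w0 * (1 + eps_own) + beta * w0
  # cooking-oil substitution: cross-price elasticity of other-oils demand
  # with respect to the palm-oil price
  eps_op <- stats::runif(1, 0.40, 0.50)
  g_po <- w0[io_] * eps_op + beta[io_] * w0[ip]
  # symmetric off-diagonal completion a_i + a_j with prescribed row sums,
  # holding the diagonal and the palm/other-oils entry fixed
  r <- -g_diag
  r[c(ip, io_)] <- r[c(ip, io_)] - g_po
  M <- matrix(1, nC, nC)
  diag(M) <- nC - 1
  M[ip, io_] <- 0; M[io_, ip] <- 0
  M[ip, ip] <- nC - 2; M[io_, io_] <- nC - 2
  a <- solve(M, r)
  gamma <- outer(a, rep(1, nC)) + outer(rep(1, nC), a)
  gamma[ip, io_] <- g_po
  gamma[io_, ip] <- g_po
  diag(gamma) <- g_diag
  dimnames(gamma) <- list(dims$commodities, dims$commodities)
  structure(list(alpha = stats::setNames(w0, dims$commodities),
                 gamma = gamma,
                 beta = stats::setNames(beta, dims$commodities),
                 alpha0 = unname(log(eh0)),
                 shares0 = stats::setNames(w0, dims$commodities)),
            class = "aids_parameters")
}

#' Generate a seeded synthetic economy with known ground truth
#'
#' Builds every calibration input the framework consumes: a balanced SAM, a
#' regularity-consistent Almost Ideal Demand System (AIDS) per household,
#' nutrient-energy coefficients, biomarker distributions and risk functions,
#' a population state, land-use-change emission coefficients and health cost
#' parameters.  Alongside the truth it returns an unbalanced SAM (the truth
#' with multiplicative lognormal noise on nonzero cells) and noisy
#' elasticity priors whose symmetry and adding-up are violated when
#' `noise_level > 0`, emulating raw literature elasticities.
#'
#' @param dims a [model_dims()] object.
#' @param seed integer seed; identical `(dims, seed, noise_level)` give
#'   bit-identical output.
#' @param noise_level non-negative standard deviation of the log-scale cell
#'   noise and of the additive elasticity perturbations.
#' @return a list with components `truth` (class `synthetic_truth`),
#'   `unbalanced_sam`, and `elasticity_priors` (named list per household).
#' @examples
#' gen <- generate_synthetic_economy(model_dims(), seed = 1)
#' max(abs(rowSums(gen$truth$balanced_sam) - colSums(gen$truth$balanced_sam)))
#' @export
generate_synthetic_economy <- function(dims = model_dims(), seed = 1L,
                                       noise_level = 0) {
  validate_dims(dims)
  if (!is.numeric(noise_level) || noise_level < 0) {
    stop("`noise_level` must be a non-negative real", call. = FALSE)
  }
  truth <- with_seed(child_seed(seed, 1L), {
    sh <- draw_economy_shares(dims)
    built <- build_balanced_sam(dims, sh)
    aids <- lapply(stats::setNames(seq_len(dims$n_households),
                                   dims$households), function(h) {
      draw_aids_truth(dims, sh$theta[, h], built$bench$EH[h])
    })
    list(sh = sh, built = built, aids = aids)
  })
  population <- generate_population(dims, seed)
  luc <- generate_luc_matrix(dims, seed)
  extra <- with_seed(child_seed(seed, 2L), {
    nutr <- draw_nutrient_coefficients(dims, truth$built$bench, population)
    bio <- draw_biomarker_distributions(dims, population)
    risks <- draw_risk_functions(dims)
    costs <- draw_cost_parameters(dims)
    yields <- draw_land_yields(dims, truth$built$bench, truth$sh)
    list(nutr = nutr, bio = bio, risks = risks, costs = costs,
         yields = yields)
  })
  strata <- initial_strata(dims, extra$bio, population)
  st <- structure(list(
    dims = dims,
    balanced_sam = truth$built$sam,
    benchmark = truth$built$bench,
    shares = truth$sh,
    aids_parameters = truth$aids,
    nutrient_coefficients = extra$nutr,
    biomarker_distributions = extra$bio,
    risk_functions = extra$risks,
    population = population,
    strata = strata,
    luc_matrix = luc,
    land_yields = extra$yields$yields,
    hectares0 = extra$yields$hectares0,
    cost_parameters = extra$costs,
    growth_targets = list(real = 0.039, nominal = 0.062)
  ), class = "synthetic_truth")

  noisy <- with_seed(child_seed(seed, 3L), {
    sam <- truth$built$sam
    nz <- sam > 0
    if (noise_level > 0) {
      sam[nz] <- sam[nz] * exp(stats::rnorm(sum(nz), 0, noise_level))
    }
    priors <- lapply(stats::setNames(dims$households, dims$households),
                     function(h) {
      p <- truth$aids[[h]]
      eps <- aids_elasticities(p)
      nC <- dims$n_commodities
      if (noise_level > 0) {
        off <- matrix(stats::rnorm(nC * nC, 0, noise_level), nC, nC)
        diag(off) <- 0
        eps$price <- eps$price + off
        eps$income <- eps$income + stats::rnorm(nC, 0, noise_level)
      }
      structure(list(eps = eps$price, eta = eps$income,
                     shares = p$shares0, expenditure0 = exp(p$alpha0)),
                class = "elasticity_priors")
    })
    list(sam = sam, priors = priors)
  })
  list(truth = st, unbalanced_sam = noisy$sam,
       elasticity_priors = noisy$priors)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", x$dims$n_commodities, "commodities,",
      x$dims$n_households, "households, GDP", signif(x$benchmark$gdp, 5),
      "\n")
  invisible(x)
}
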