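# Almost Ideal Demand System: elasticity inversion, regularity-constrained
# estimation, and demand evaluation.

#' Uncompensated elasticities implied by AIDS parameters
#'
#' Applies the standard linear-approximate (Stone price index) formulas at
#' the base budget shares: `eps_ij = -delta_ij + (gamma_ij - beta_i w_j) /
#' w_i` and `eta_i = 1 + beta_i / w_i`.
#'
#' @param params an `aids_parameters` object.
#' @return list with `price` (matrix) and `income` (vector) elasticities.
#' @export
aids_elasticities <- function(params) {
  w <- params$shares0
  n <- length(w)
  eps <- (params$gamma - outer(params$beta, w)) / w - diag(n)
  dimnames(eps) <- dimnames(params$gamma)
  list(price = eps, income = 1 + params$beta / w)
}

#' Invert elasticities into prior AIDS parameters
#'
#' Inverts the linear-approximate elasticity formulas at the base budget
#' shares to obtain prior intercepts, price and expenditure coefficients:
#' `beta_i = w_i (eta_i - 1)`, `gamma_ij = w_i (eps_ij + delta_ij) + beta_i
#' w_j`, `alpha_i = w_i` (with the price-index anchor set to the log of base
#' expenditure so benchmark shares reproduce at unit prices).  The output
#' generally violates regularity when the input elasticities do; use
#' [estimate_aids()] to impose it.
#'
#' @param priors an `elasticity_priors` object (fields `eps`, `eta`,
#'   `shares`, `expenditure0`).
#' @return an `aids_parameters` object.
#' @export
elasticities_to_aids <- function(priors) {
  w <- priors$shares
  if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1)) {
    bad <- names(w)[which(w <= 0 | w >= 1 | !is.finite(w))]
    stop("invalid budget share for commodity: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(w)
  beta <- w * (priors$eta - 1)
  gamma <- w * (priors$eps + diag(n)) + outer(beta, w)
  dimnames(gamma) <- dimnames(priors$eps)
  structure(list(alpha = w, gamma = gamma, beta = beta,
                 alpha0 = unname(log(priors$expenditure0 %||% 1)),
                 shares0 = w),
            class = "aids_parameters")
}

#' Regularity residuals of AIDS parameters
#'
#' @param params an `aids_parameters` object.
#' @return named vector of maximum absolute violations of adding-up,
#'   homogeneity and symmetry.
#' @export
aids_constraint_residuals <- function(params) {
  g <- params$gamma
  c(adding_up_alpha = abs(sum(params$alpha) - 1),
    adding_up_beta = abs(sum(params$beta)),
    adding_up_gamma = max(abs(colSums(g))),
    homogeneity = max(abs(rowSums(g))),
    symmetry = max(abs(g - t(g))))
}

#' Impose AIDS regularity by minimum weighted divergence
#'
#' Finds the posterior parameter set closest to the prior in weighted
#' squared deviation (Gaussian cross-entropy) subject to the full set of
#' regularity constraints: adding-up (`sum(alpha) = 1`, `sum(beta) = 0`,
#' zero column sums of gamma), homogeneity (zero row sums) and Slutsky
#' symmetry.  The constraints are linear, so the program is an
#' equality-constrained quadratic problem solved exactly through its KKT
#' system; the implied posterior elasticities then satisfy Engel
#' aggregation and Cournot adding-up by construction.
#'
#' @param prior_params an `aids_parameters` object.
#' @param weights optional list with `alpha`, `beta` (vectors) and `gamma`
#'   (matrix) of positive precisions; default all ones.
#' @return an `aids_parameters` object satisfying all constraints to
#'   numerical precision.
#' @export
estimate_aids <- function(prior_params, weights = NULL) {
  g0 <- prior_params$gamma
  n <- nrow(g0)
  wts <- list(
    alpha = rep(1, n), beta = rep(1, n),
    gamma = matrix(1, n, n)
  )
  if (!is.null(weights)) wts[names(weights)] <- weights
  if (any(unlist(wts) <= 0)) stop("weights must be positive", call. = FALSE)

  proj_sum <- function(x, w, target) {
    x + (target - sum(x)) * (1 / w) / sum(1 / w)
  }
  alpha <- proj_sum(prior_params$alpha, wts$alpha, 1)
  beta <- proj_sum(prior_params$beta, wts$beta, 0)

  # gamma: KKT system for min .5*(g-g0)'W(g-g0) s.t. rowSums = 0, symmetry
  wv <- as.numeric(wts$gamma)
  idx <- function(i, j) (j - 1L) * n + i
  n_hom <- n
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  n_sym <- nrow(pairs)
  A <- matrix(0, n_hom + n_sym, n * n)
  for (i in seq_len(n)) A[i, idx(i, seq_len(n))] <- 1
  for (k in seq_len(n_sym)) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    A[n_hom + k, idx(i, j)] <- 1
    A[n_hom + k, idx(j, i)] <- -1
  }
  # eliminate gamma: g = g0 - W^-1 A' nu, with A g = 0
  AWinv <- sweep(A, 2L, wv, `/`)
  M <- AWinv %*% t(A)
  rhs <- A %*% as.numeric(g0)
  nu <- solve(M + diag(1e-14, nrow(M)), rhs)
  gvec <- as.numeric(g0) - as.numeric(t(AWinv) %*% nu)
  gamma <- matrix(gvec, n, n, dimnames = dimnames(g0))
  gamma <- (gamma + t(gamma)) / 2                # clean symmetry exactly
  gamma <- gamma - rowSums(gamma) / n            # and re-centre rows
  gamma <- (gamma + t(gamma)) / 2

  structure(list(alpha = alpha, gamma = gamma, beta = beta,
                 alpha0 = prior_params$alpha0,
                 shares0 = prior_params$shares0),
            class = "aids_parameters")
}

#' AIDS budget shares at given prices and expenditure
#'
#' Uses the full translog price index `ln P = alpha0 + sum(alpha*ln p) +
#' .5 * ln p' Gamma ln p`, anchored so benchmark shares reproduce at unit
#' prices and base expenditure.
#'
#' @param params an `aids_parameters` object.
#' @param prices positive consumer price vector.
#' @param expenditure total consumption expenditure.
#' @return vector of budget shares.
#' @export
aids_shares <- function(params, prices, expenditure) {
  lp <- log(prices)
  lnP <- params$alpha0 + sum(params$alpha * lp) +
    0.5 * sum(lp * (params$gamma %*% lp))
  as.numeric(params$alpha + params$gamma %*% lp +
               params$beta * (log(expenditure) - lnP))
}

#' AIDS demanded quantities
#'
#' @inheritParams aids_shares
#' @return vector of quantities `w * expenditure / prices`.
#' @export
aids_quantities <- function(params, prices, expenditure) {
  aids_shares(params, prices, expenditure) * expenditure / prices
}

#' @export
print.aids_parameters <- function(x, ...) {
  res <- aids_constraint_residuals(x)
  cat("<aids_parameters>", length(x$alpha), "commodities; max regularity",
      "residual", signif(max(res), 3), "\n")
  invisible(x)
}
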