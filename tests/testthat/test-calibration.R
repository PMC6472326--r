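# Cross-entropy SAM balancing and regularity-constrained AIDS estimation.

test_that("an already balanced prior is returned unchanged", {
  sam <- test_gen()$truth$balanced_sam
  out <- balance_sam(sam)
  expect_lt(max(abs(out - sam)) / max(sam), 1e-10)
})

test_that("balancing a perturbed 3x3 prior matches a generic optimizer", {
  acc <- c("a", "b", "c")
  prior <- matrix(c(0, 2, 1,
                    1, 0, 2,
                    2, 1, 0), 3, 3, byrow = TRUE,
                  dimnames = list(acc, acc))
  prior[1, 2] <- 1.4   # perturb one cell
  out <- balance_sam(prior)
  expect_lt(max(abs(rowSums(out) - colSums(out))) / max(rowSums(out)), 1e-8)
  expect_true(all((out == 0) == (prior == 0)))

  # oracle: minimize the same I-divergence over an explicit null-space
  # parameterization of the balance constraints (independent of the dual
  # Newton path used by balance_sam)
  pos <- which(prior > 0)
  A <- matrix(0, 2, length(pos))   # net-flow constraints of accounts 1, 2
  for (j in seq_along(pos)) {
    rc <- arrayInd(pos[j], dim(prior))
    for (i in 1:2) A[i, j] <- (rc[1] == i) - (rc[2] == i)
  }
  N <- svd(A, nv = length(pos))$v[, 3:6]   # null-space basis
  a0 <- rep(1, length(pos))                # feasible start (all equal)
  obj <- function(t) {
    a <- a0 + as.numeric(N %*% t)
    if (any(a <= 0)) return(1e6)
    sum(a * log(a / prior[pos]) - a + prior[pos])
  }
  fit <- stats::optim(rep(0, 4), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  oracle <- a0 + as.numeric(N %*% fit$par)
  expect_equal(out[pos], oracle, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("an infeasible zero pattern raises a named error", {
  acc <- c("a", "b", "c")
  prior <- matrix(c(0, 0, 0,
                    1, 0, 2,
                    2, 1, 0), 3, 3, byrow = TRUE,
                  dimnames = list(acc, acc))
  expect_error(balance_sam(prior), "`a`")
})

test_that("balance_sam is idempotent and honours explicit targets", {
  g <- generate_synthetic_economy(test_dims(), seed = 3, noise_level = 0.08)
  b1 <- balance_sam(g$unbalanced_sam)
  b2 <- balance_sam(b1)
  expect_lt(max(abs(b2 - b1)) / max(b1), 1e-9)
  tgt <- rowSums(g$truth$balanced_sam)
  bt <- balance_sam(g$unbalanced_sam, targets = tgt)
  expect_equal(unname(rowSums(bt)), unname(tgt), tolerance = 1e-8)
  expect_equal(unname(colSums(bt)), unname(tgt), tolerance = 1e-8)
})

test_that("elasticity inversion has the textbook closed forms", {
  w <- c(0.4, 0.35, 0.25)
  n <- 3
  # homothetic: unit income elasticities imply zero expenditure coefficients
  pr <- structure(list(eps = -diag(n), eta = rep(1, n), shares = w,
                       expenditure0 = 10), class = "elasticity_priors")
  p <- elasticities_to_aids(pr)
  expect_equal(p$beta, w * 0, ignore_attr = TRUE)
  # Cobb-Douglas pattern: gamma and beta vanish
  expect_equal(max(abs(p$gamma)), 0, tolerance = 1e-15)
  # zero budget share is a reported error
  bad <- pr; bad$shares[2] <- 0
  expect_error(elasticities_to_aids(bad), "budget share")
})

test_that("forward elasticity formulas invert the inversion", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 4
    w <- rdirichlet1(rep(4, n))
    eps <- matrix(rnorm(n * n, 0, 0.2), n, n) - diag(n)
    eta <- runif(n, 0.8, 1.2)
    pr <- structure(list(eps = eps, eta = eta, shares = w,
                         expenditure0 = 5), class = "elasticity_priors")
    p <- elasticities_to_aids(pr)
    back <- aids_elasticities(p)
    expect_lt(max(abs(back$price - eps)), 1e-10)
    expect_lt(max(abs(back$income - eta)), 1e-10)
  }
})

test_that("a regular prior passes through estimation unchanged", {
  p <- test_gen()$truth$aids_parameters[[1]]
  post <- estimate_aids(p)
  expect_lt(max(abs(post$gamma - p$gamma)), 1e-8)
  expect_lt(max(abs(post$alpha - p$alpha)), 1e-12)
  expect_lt(max(abs(post$beta - p$beta)), 1e-12)
})

test_that("a pure symmetry violation resolves to the midpoint", {
  p <- test_gen()$truth$aids_parameters[[1]]
  eps <- 0.02
  prior <- p
  prior$gamma[1, 2] <- prior$gamma[1, 2] + eps
  prior$gamma[2, 1] <- prior$gamma[2, 1] - eps
  post <- estimate_aids(prior)
  mid <- (prior$gamma[1, 2] + prior$gamma[2, 1]) / 2
  expect_equal(post$gamma[1, 2], mid, tolerance = 1e-6)
  expect_equal(post$gamma[2, 1], mid, tolerance = 1e-6)
  expect_lt(max(aids_constraint_residuals(post)), 1e-8)
})

test_that("posterior parameters recover the truth better than the prior", {
  d <- test_dims()
  wins <- 0L
  for (seed in 1:8) {
    g <- generate_synthetic_economy(d, seed = seed, noise_level = 0.08)
    tr <- g$truth
    sam_post <- balance_sam(g$unbalanced_sam)
    sam_better <- norm(sam_post - tr$balanced_sam, "F") <
      norm(g$unbalanced_sam - tr$balanced_sam, "F")
    aids_better <- TRUE
    for (h in d$households) {
      prior <- elasticities_to_aids(g$elasticity_priors[[h]])
      post <- estimate_aids(prior)
      truth <- tr$aids_parameters[[h]]
      dist <- function(p) {
        sqrt(norm(p$gamma - truth$gamma, "F")^2 +
               sum((p$beta - truth$beta)^2) + sum((p$alpha - truth$alpha)^2))
      }
      aids_better <- aids_better && dist(post) < dist(prior)
    }
    wins <- wins + (sam_better && aids_better)
  }
  expect_gte(wins, 7L)
})

test_that("estimation is invariant to commodity ordering", {
  g <- test_gen()
  prior <- elasticities_to_aids(g$elasticity_priors[[2]])
  post <- estimate_aids(prior)
  n <- length(prior$alpha)
  perm <- c(3, 1, 2, seq(4, n))
  prior_p <- prior
  prior_p$alpha <- prior$alpha[perm]
  prior_p$beta <- prior$beta[perm]
  prior_p$shares0 <- prior$shares0[perm]
  prior_p$gamma <- prior$gamma[perm, perm]
  post_p <- estimate_aids(prior_p)
  expect_equal(post_p$gamma, post$gamma[perm, perm], tolerance = 1e-10)
  expect_equal(post_p$beta, post$beta[perm], tolerance = 1e-12)
})

test_that("posterior demand satisfies adding-up and zero homogeneity", {
  g <- test_gen()
  prior <- elasticities_to_aids(g$elasticity_priors[[1]])
  post <- estimate_aids(prior)
  set.seed(99)
  for (i in 1:50) {
    p <- exp(rnorm(length(post$alpha), 0, 0.3))
    e <- exp(post$alpha0 + rnorm(1, 0, 0.3))
    w <- aids_shares(post, p, e)
    expect_equal(sum(w), 1, tolerance = 1e-10)
    lam <- runif(1, 0.5, 2)
    expect_equal(aids_shares(post, lam * p, lam * e), w, tolerance = 1e-10)
    q <- aids_quantities(post, p, e)
    expect_equal(sum(q * p), e, tolerance = 1e-8 * e)
  }
})
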