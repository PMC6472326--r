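# Minimum cross-entropy balancing of social accounting matrices.

#' Check whether a SAM is balanced
#'
#' A SAM is balanced when every account's row sum (income) equals its
#' column sum (expenditure) to the given relative tolerance.
#'
#' @param sam square non-negative matrix with account dimnames.
#' @param tol relative tolerance.
#' @return logical.
#' @export
is_balanced_sam <- function(sam, tol = 1e-8) {
  scale <- max(rowSums(sam), 1e-12)
  max(abs(rowSums(sam) - colSums(sam))) / scale <= tol
}

#' Balance a prior SAM by minimum cross-entropy
#'
#' Finds the non-negative matrix closest to the prior in generalized
#' cross-entropy (I-divergence, `sum(a*log(a/p) - a + p)`) subject to every
#' account's income equalling its expenditure; structural zeros of the prior
#' are preserved.  The first-order conditions give `a_ij = p_ij *
#' exp(lambda_j - lambda_i)`, so the problem reduces to a small concave
#' root-finding problem in the account potentials, solved by Newton's
#' method.  When `targets` (named account totals) are supplied the matrix is
#' instead scaled to those row and column totals by iterative proportional
#' fitting, which solves the corresponding cross-entropy program.
#'
#' @param prior square non-negative matrix (account x account).
#' @param targets optional named vector of account totals.
#' @param tol relative balance tolerance of the returned SAM.
#' @param maxit maximum Newton / scaling iterations.
#' @return a balanced SAM with the prior's zero pattern.
#' @examples
#' p <- matrix(c(0, 2, 1, 1, 0, 2, 2, 1, 0), 3, 3,
#'             dimnames = rep(list(c("a", "b", "c")), 2))
#' b <- balance_sam(p)
#' max(abs(rowSums(b) - colSums(b)))
#' @export
balance_sam <- function(prior, targets = NULL, tol = 1e-10, maxit = 200L) {
  if (!is.matrix(prior) || nrow(prior) != ncol(prior)) {
    stop("`prior` must be a square matrix", call. = FALSE)
  }
  if (any(prior < 0)) stop("`prior` cells must be non-negative", call. = FALSE)
  n <- nrow(prior)
  acc <- rownames(prior) %||% paste0("acct", seq_len(n))

  if (!is.null(targets)) {
    return(balance_sam_ipf(prior, targets, tol, maxit))
  }

  rs <- rowSums(prior); cs <- colSums(prior)
  dead_row <- rs == 0 & cs > 0
  dead_col <- cs == 0 & rs > 0
  if (any(dead_row | dead_col)) {
    bad <- acc[which(dead_row | dead_col)[1L]]
    stop("infeasible zero pattern: account `", bad,
         "` has structurally zero ", if (any(dead_row)) "income" else
           "expenditure", " but a positive counterpart total", call. = FALSE)
  }
  active <- which(rs + cs > 0)
  if (!length(active)) return(prior)

  lambda <- numeric(n)
  scale <- max(rs)
  free <- setdiff(active, active[which.max(rs[active] + cs[active])])
  p <- prior
  for (it in seq_len(maxit)) {
    a <- p * exp(outer(-lambda, lambda, `+`))
    g <- rowSums(a) - colSums(a)
    if (max(abs(g)) <= tol * scale) break
    if (!length(free)) break
    s <- a + t(a)
    J <- s
    diag(J) <- 0
    diag(J) <- -rowSums(J)
    step <- solve(J[free, free, drop = FALSE] -
                    diag(1e-14 * scale, length(free)), -g[free])
    step <- pmin(pmax(step, -2), 2)              # damp large potential moves
    lambda[free] <- lambda[free] + step
    if (it == maxit) warning("balance_sam: maximum iterations reached")
  }
  out <- p * exp(outer(-lambda, lambda, `+`))
  dimnames(out) <- dimnames(prior)
  out
}

balance_sam_ipf <- function(prior, targets, tol, maxit) {
  n <- nrow(prior)
  acc <- rownames(prior) %||% paste0("acct", seq_len(n))
  t_vec <- targets[acc]
  if (anyNA(t_vec)) stop("`targets` must name every account", call. = FALSE)
  a <- prior
  for (it in seq_len(maxit)) {
    rs <- rowSums(a)
    r <- ifelse(rs > 0, t_vec / rs, 1)
    a <- a * r
    cs <- colSums(a)
    s <- ifelse(cs > 0, t_vec / cs, 1)
    a <- sweep(a, 2L, s, `*`)
    if (max(abs(rowSums(a) - t_vec), abs(colSums(a) - t_vec)) <=
        tol * max(t_vec)) break
  }
  dimnames(a) <- dimnames(prior)
  a
}
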