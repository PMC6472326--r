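# Internal numerical helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators are
#' reproducible without disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a user seed so that independent
# generators do not share random streams. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 8191) %% 2147483647
}

#' Damped Newton solver for square nonlinear systems
#'
#' Solves f(x) = 0 with a forward-difference Jacobian and step halving.
#' Residual reduction is measured in the max norm.
#'
#' @param f residual function returning a numeric vector of `length(x0)`.
#' @param x0 starting point.
#' @param tol convergence tolerance on `max(abs(f(x)))`.
#' @param maxit maximum Newton iterations.
#' @param h finite-difference step.
#' @return list with `x`, `fval`, `converged`, `iterations`.
#' @keywords internal
newton_solve <- function(f, x0, tol = 1e-10, maxit = 60L, h = 1e-7) {
  x <- x0
  fx <- f(x)
  n <- length(x)
  if (length(fx) != n) stop("newton_solve: system is not square", call. = FALSE)
  for (it in seq_len(maxit)) {
    nf <- max(abs(fx))
    if (!is.finite(nf)) stop("newton_solve: non-finite residual", call. = FALSE)
    if (nf < tol) {
      return(list(x = x, fval = fx, converged = TRUE, iterations = it - 1L))
    }
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      dx <- h * max(1, abs(x[j]))
      xp <- x
      xp[j] <- xp[j] + dx
      J[, j] <- (f(xp) - fx) / dx
    }
    step <- tryCatch(solve(J, -fx), error = function(e) {
      # near-singular Jacobian: fall back to a ridge-regularized step
      ridge <- 1e-8 * max(abs(J))
      solve(J + diag(ridge, n), -fx)
    })
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- tryCatch(f(xn), error = function(e) rep(NA_real_, n))
      if (all(is.finite(fn)) && max(abs(fn)) < nf) break
      lam <- lam / 2
      if (lam < 1e-6) {
        # accept a tiny step if finite; otherwise fail below
        if (all(is.finite(fn))) break
        stop("newton_solve: line search failed; residual ", signif(nf, 6),
             call. = FALSE)
      }
    }
    x <- xn
    fx <- fn
  }
  list(x = x, fval = fx, converged = max(abs(fx)) < tol, iterations = maxit)
}

# Scalar root bracketing + refinement (monotone-ish functions). Used for the
# per-period productivity shifter and the sales-tax search.
bracket_root <- function(f, lower, upper, tol = 1e-9, maxit = 100L,
                         f_lower = NULL, f_upper = NULL) {
  fl <- if (is.null(f_lower)) f(lower) else f_lower
  fu <- if (is.null(f_upper)) f(upper) else f_upper
  if (fl == 0) return(list(root = lower, froot = 0))
  if (fu == 0) return(list(root = upper, froot = 0))
  if (fl * fu > 0) {
    stop("bracket_root: no sign change on [", lower, ", ", upper, "]",
         call. = FALSE)
  }
  a <- lower; b <- upper; fa <- fl; fb <- fu
  for (i in seq_len(maxit)) {
    # secant proposal, safeguarded by bisection
    m <- if (abs(fb - fa) > 0) b - fb * (b - a) / (fb - fa) else (a + b) / 2
    if (!is.finite(m) || m <= a || m >= b) m <- (a + b) / 2
    fm <- f(m)
    if (abs(fm) < tol || (b - a) < tol * max(1, abs(m))) {
      return(list(root = m, froot = fm))
    }
    if (fa * fm <= 0) { b <- m; fb <- fm } else { a <- m; fa <- fm }
  }
  list(root = (a + b) / 2, froot = f((a + b) / 2))
}

# Dirichlet draw via gamma variates.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
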