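#' @keywords internal
"_PACKAGE"

# Numerically safe log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive reproducible child seeds from a master seed
#'
#' Spawns `n` integer seeds deterministically from one master seed, without
#' disturbing the caller's random-number state. The derivation is
#' prefix-stable: the first `k` seeds are the same whatever `n >= k` is
#' requested, so adding clones or replicates to an experiment never perturbs
#' the draws of earlier ones.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, each usable with [set.seed()].
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  if (n == 0) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  # sequential draws => prefix-stable
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' random-number state, so seeded simulation steps never perturb surrounding
#' draws.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Ridge-penalized logistic regression by damped Newton/IRLS.
# X: n x p design (no intercept column), y in {0,1}. All coefficients
# (including the intercept) carry the L2 penalty, so the objective is
# strictly concave with a unique finite optimum even on separable data.
# Returns c(intercept, weights).
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L, tol = 1e-9,
                           start = NULL) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  obj <- function(b) {
    eta <- drop(X1 %*% b)
    # stable log(1 + e^eta)
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    sum(y * eta - lse) - lambda / 2 * sum(b^2)
  }
  b <- if (is.null(start) || any(!is.finite(start))) numeric(p) else start
  f <- obj(b)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X1, y - mu)) - lambda * b
    H <- crossprod(X1 * w, X1) + diag(lambda, p)
    step <- solve(H, g)
    s <- 1
    repeat {                     # halve until the penalized loglik improves
      b_new <- b + s * step
      f_new <- obj(b_new)
      if (f_new >= f - 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    moved <- max(abs(s * step))
    b <- b_new
    f <- f_new
    if (moved < tol) break
  }
  drop(b)
}
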