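# Per-trial causal count statistics, precomputed once per stimulus.
#
# For every trial t and every order R <= r_max, the observer about to predict
# trial t knows the counts over sliding windows ending strictly before t:
#   ncs[t, R+1, s+1] = # { i : R < i < t, context_R(i) == context_R(t),
#                          x[i] == s (and retained, if a retention mask) }
# where context_R(t) is the length-R suffix x[t-R..t-1]. nc is the row total
# n(c). These arrays are the complete sufficient statistics for every n-gram
# emission stream and for incremental Dirichlet-multinomial evidence, so a
# grid of (alpha, beta, gamma) values can be evaluated by vectorized
# arithmetic with no re-counting.
count_trace <- function(x, r_max, A = 2L, retain = NULL) {
  N <- length(x)
  r_max <- as.integer(r_max)
  ncs <- array(0, c(N, r_max + 1L, A))
  valid <- matrix(FALSE, N, r_max + 1L)
  if (N > 0L) {
    for (R in 0:r_max) {
      if (N < R + 1L) next
      pos <- (R + 1L):N
      k <- rep(1, length(pos))
      if (R > 0L) for (j in seq_len(R)) k <- k + x[pos - j] * A^(j - 1L)
      for (s in 0:(A - 1L)) {
        I <- as.numeric(x[pos] == s)
        if (!is.null(retain)) I <- I * retain[pos]
        incl <- stats::ave(I, k, FUN = cumsum)
        ncs[pos, R + 1L, s + 1L] <- incl - I   # exclusive (strictly-before) count
      }
      valid[pos, R + 1L] <- TRUE
    }
  }
  nc <- matrix(0, N, r_max + 1L)
  for (s in seq_len(A)) nc <- nc + ncs[, , s, drop = FALSE][, , 1L]
  list(x = x, N = N, A = A, r_max = r_max, ncs = ncs, nc = nc, valid = valid)
}

# Emission stream of the n-gram argmax observer on a precomputed count trace.
# Per trial: Dirichlet-multinomial log evidence for each order (accumulated
# incrementally), MAP order R* under the e^{-gamma(A-1)A^R} prior with ties
# to the smaller order, then the MAP-parameter predictive at R*.
stream_ngram_argmax <- function(tr, alpha, beta, gamma) {
  if (alpha < 1) stop("ngram_argmax requires alpha >= 1")
  A <- tr$A; N <- tr$N; r_max <- tr$r_max
  p <- matrix(1 / A, N, A)
  if (N == 0L) return(p)
  orders <- 0:r_max
  # evidence increment contributed by the window ending at trial t
  n_obs <- matrix(0, N, r_max + 1L)
  for (s in 0:(A - 1L)) {
    rows <- which(tr$x == s)
    if (length(rows)) n_obs[rows, ] <- tr$ncs[rows, , s + 1L, drop = FALSE][, , 1L]
  }
  delta <- lgamma(beta * (n_obs + 1) + alpha) - lgamma(beta * n_obs + alpha) -
    lgamma(beta * (tr$nc + 1) + A * alpha) + lgamma(beta * tr$nc + A * alpha)
  delta[!tr$valid] <- 0
  cs <- apply(delta, 2L, cumsum)
  if (N == 1L) cs <- matrix(cs, nrow = 1L)
  logev_before <- rbind(0, cs[-N, , drop = FALSE])
  scores <- sweep(logev_before, 2L,
                  -gamma * (A - 1) * A^orders, "+")
  scores[!tr$valid] <- -Inf              # R* must have a realized context
  rstar <- max.col(scores, ties.method = "first") - 1L
  sel <- cbind(seq_len(N), rstar + 1L)
  den <- A * (alpha - 1) + beta * tr$nc[sel]
  for (s in seq_len(A)) {
    ncs_s <- tr$ncs[, , s, drop = FALSE][, , 1L, drop = FALSE]
    dim(ncs_s) <- dim(tr$nc)
    num <- alpha - 1 + beta * ncs_s[sel]
    p[, s] <- ifelse(den <= 1e-12, 1 / A, num / den)
  }
  p[1L, ] <- 1 / A                       # no history at trial 1
  attr(p, "map_orders") <- rstar
  p
}

# Emission stream of the n-gram average observer: the prior-weighted mixture
# of per-order posterior-mean predictives, truncated at min(r_max, t - 1)
# with the prior weights renormalized over the realized orders.
stream_ngram_average <- function(tr, alpha, beta, gamma) {
  if (alpha <= 0) stop("alpha must be positive")
  A <- tr$A; N <- tr$N; r_max <- tr$r_max
  p <- matrix(1 / A, N, A)
  if (N == 0L) return(p)
  w <- exp(-gamma * (A - 1) * A^(0:r_max))
  Z <- drop(tr$valid %*% w)
  ok <- Z > 0
  for (s in seq_len(A)) {
    ncs_s <- tr$ncs[, , s, drop = FALSE][, , 1L, drop = FALSE]
    dim(ncs_s) <- dim(tr$nc)
    Tm <- (alpha + beta * ncs_s) / (A * alpha + beta * tr$nc)
    Tm[!tr$valid] <- 0
    p[ok, s] <- drop(Tm %*% w)[ok] / Z[ok]
  }
  p
}

# Emission stream of the GLM observer: at each trial, ridge-penalized
# logistic regression of the next symbol on the raw values of the last k
# symbols, refit on all (window, next-symbol) pairs seen so far; uniform
# until at least k + 2 training pairs exist. Binary alphabets only.
stream_glm <- function(x, k, ridge = 1e-4) {
  N <- length(x)
  p <- matrix(0.5, N, 2L)
  if (N == 0L) return(p)
  k <- as.integer(k)
  if (k < 1L) stop("window must be >= 1")
  n_pairs_total <- max(N - k, 0L)
  if (n_pairs_total > 0L) {
    X <- matrix(0, n_pairs_total, k)
    for (j in seq_len(k)) X[, j] <- x[(k + 1L):N - j]
    y <- x[(k + 1L):N]
    coef <- NULL
    for (t in seq_len(N)) {
      n_pairs <- t - 1L - k
      if (n_pairs < k + 2L) next
      rows <- seq_len(n_pairs)
      coef <- ridge_logistic(X[rows, , drop = FALSE], y[rows], lambda = ridge,
                             start = coef)
      win <- x[t - seq_len(k)]           # most recent first, matching X
      p1 <- plogis(coef[1L] + sum(coef[-1L] * win))
      p[t, ] <- c(1 - p1, p1)
    }
  }
  p
}
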