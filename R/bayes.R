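#' Log prior over Markov orders
#'
#' The complexity-penalizing prior over model topologies,
#' `P(M_R) proportional to exp(-gamma (|A|-1) |A|^R)`: the exponent is (minus
#' gamma times) the number of free transition parameters of an order-R model.
#' Returned unnormalized, in log space.
#'
#' @param R Markov order (vectorized).
#' @param gamma Complexity penalty, `gamma >= 0`.
#' @param alphabet_size `|A| >= 2`.
#' @return `-gamma * (|A|-1) * |A|^R`.
#' @export
log_prior_order <- function(R, gamma, alphabet_size = 2L) {
  stopifnot(all(R >= 0), gamma >= 0, alphabet_size >= 2)
  -gamma * (alphabet_size - 1) * alphabet_size^R
}

#' Log evidence of an order-R Markov model
#'
#' The Dirichlet-multinomial marginal likelihood of the observed
#' context/symbol counts under a symmetric Dirichlet(`alpha`) prior on each
#' context's emission vector, with every count discounted by the data-use
#' weight `beta` (`n -> beta * n`, the observer's memory limitation):
#' for each context `c`,
#' `log G(|A| a) - |A| log G(a) + sum_s log G(b n(c s) + a) - log G(b n(c) + |A| a)`.
#' An empty sequence (or `beta = 0`) gives exactly 0.
#'
#' @param counts A [count_contexts()] object.
#' @param R Order at which to evaluate, `R <= counts$max_order`.
#' @param alpha Dirichlet concentration, `alpha > 0`.
#' @param beta Data-use weight in `[0, 1]`.
#' @return Log marginal likelihood (a nonpositive real for `alpha <= 1`).
#' @export
log_evidence_order <- function(counts, R, alpha, beta = 1) {
  stopifnot(inherits(counts, "context_counts"))
  if (alpha <= 0) stop("alpha must be positive")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (R < 0 || R > counts$max_order)
    stop("R must be between 0 and counts$max_order")
  A <- counts$alphabet$size
  m <- counts_ncs(counts, R)
  nc <- rowSums(m)
  keep <- nc > 0
  if (!any(keep) || beta == 0) return(0)
  m <- m[keep, , drop = FALSE]
  nc <- nc[keep]
  sum(lgamma(A * alpha) - A * lgamma(alpha) +
        rowSums(lgamma(beta * m + alpha)) - lgamma(beta * nc + A * alpha))
}

#' Posterior over Markov orders
#'
#' Combines [log_prior_order()] and [log_evidence_order()] for
#' `R = 0..r_max`, normalizes over that range, and records the MAP order
#' `R*` (ties broken toward the smaller, simpler order).
#'
#' @inheritParams log_evidence_order
#' @param gamma Complexity penalty.
#' @param r_max Truncation order, `r_max <= counts$max_order`.
#' @return An object of class `"order_posterior"`: list with `r_max`,
#'   `alpha`, `beta`, `gamma`, per-order `log_prior`, `log_evidence`,
#'   `log_posterior` (normalized), `map_order`, and `z_prior` (the prior
#'   normalizer over `R <= r_max`).
#' @export
order_posterior <- function(counts, alpha = 1, beta = 1, gamma = 0.1,
                            r_max = counts$max_order) {
  stopifnot(inherits(counts, "context_counts"))
  if (r_max > counts$max_order) stop("r_max must be <= counts$max_order")
  A <- counts$alphabet$size
  orders <- 0:r_max
  lp <- log_prior_order(orders, gamma, A)
  le <- vapply(orders, function(R) log_evidence_order(counts, R, alpha, beta),
               numeric(1))
  joint <- lp + le
  lpost <- joint - logsumexp(joint)
  structure(list(r_max = as.integer(r_max), alpha = alpha, beta = beta,
                 gamma = gamma,
                 log_prior = stats::setNames(lp, orders),
                 log_evidence = stats::setNames(le, orders),
                 log_posterior = stats::setNames(lpost, orders),
                 map_order = orders[which.max(joint)],
                 z_prior = sum(exp(lp))),
            class = "order_posterior")
}

#' @export
print.order_posterior <- function(x, ...) {
  cat(sprintf("posterior over Markov orders 0..%d (alpha=%g, beta=%g, gamma=%g)\n",
              x$r_max, x$alpha, x$beta, x$gamma))
  print(round(exp(x$log_posterior), 4))
  cat("MAP order R* =", x$map_order, "\n")
  invisible(x)
}

#' MAP-parameter predictive of the n-gram argmax observer
#'
#' The probability the argmax observer assigns to `symbol` after context
#' `context` at its MAP order: the mode of the Dirichlet posterior with
#' beta-discounted counts,
#' `(alpha + beta n(c s) - 1) / (|A|(alpha - 1) + beta n(c))`.
#' When the denominator vanishes (the `alpha = 1`, no-data case) the uniform
#' `1/|A|` is returned. `alpha < 1` is an error: the Dirichlet mode is not
#' defined in the interior there.
#'
#' @inheritParams log_evidence_order
#' @param map_order The order `R*` whose context is conditioned on.
#' @param context Context string of length `map_order` (`""` for order 0),
#'   most recent symbol last.
#' @param symbol 0-based symbol index.
#' @return A probability.
#' @export
predictive_argmax <- function(counts, alpha, beta, map_order, context,
                              symbol) {
  stopifnot(inherits(counts, "context_counts"))
  if (alpha < 1) stop("ngram_argmax requires alpha >= 1")
  A <- counts$alphabet$size
  if (nchar(context) != map_order)
    stop("context length must equal map_order")
  m <- counts_ncs(counts, map_order)
  row <- if (map_order == 0L) 1L else match(context, rownames(m))
  if (is.na(row)) stop("unknown context: ", context)
  n_cs <- m[row, symbol + 1L]
  n_c <- sum(m[row, ])
  den <- A * (alpha - 1) + beta * n_c
  if (den <= 1e-12) return(1 / A)
  (alpha - 1 + beta * n_cs) / den
}

#' Prior-weighted average predictive of the n-gram average observer
#'
#' The mixture over orders `R = 0..r_max` of each order's posterior-mean
#' (Laplace-smoothed) predictive `(alpha + beta n(c_R s)) / (|A| alpha +
#' beta n(c_R))`, weighted by the normalized order prior
#' `exp(-gamma (|A|-1) |A|^R) / Z`, where `c_R` is the length-R suffix of
#' `history`.
#'
#' @inheritParams order_posterior
#' @param history Integer 0-based symbol sequence the observer has seen; must
#'   be at least `r_max` long so every suffix context exists.
#' @param symbol 0-based symbol index to score.
#' @return A probability.
#' @export
predictive_average <- function(counts, alpha, beta, gamma, r_max, history,
                               symbol) {
  stopifnot(inherits(counts, "context_counts"))
  if (alpha <= 0) stop("alpha must be positive")
  if (r_max > counts$max_order) stop("r_max must be <= counts$max_order")
  if (r_max > length(history))
    stop("r_max exceeds the available history length")
  A <- counts$alphabet$size
  ab <- counts$alphabet
  orders <- 0:r_max
  w <- exp(log_prior_order(orders, gamma, A))
  terms <- vapply(orders, function(R) {
    m <- counts_ncs(counts, R)
    ctx <- if (R == 0L) "" else
      paste(ab$symbols[utils::tail(history, R) + 1L], collapse = "")
    row <- if (R == 0L) 1L else match(ctx, rownames(m))
    (alpha + beta * m[row, symbol + 1L]) / (A * alpha + beta * sum(m[row, ]))
  }, numeric(1))
  sum(w * terms) / sum(w)
}

#' Asymptotic MAP order of the argmax observer
#'
#' Large-`t` approximation to the MAP Markov order: the argmax over
#' `R <= r_max` of
#' `-(|A|-1)|A|^R gamma + |A|^R log[G(|A| alpha)/G(alpha)^|A|] - t h(R)`,
#' where `h(R)` is the stimulus's conditional entropy curve in nats. Larger
#' `t` rewards orders with lower conditional entropy; larger `gamma` pushes
#' `R*` down. Ties break toward the smaller order.
#'
#' @param alpha Concentration parameter.
#' @param gamma Complexity penalty.
#' @param t Number of trials observed.
#' @param entropy_curve Numeric vector `h(0..r_max)` in nats (see
#'   [entropy_curve()]).
#' @param r_max Largest order considered.
#' @param alphabet_size `|A|`.
#' @return The approximate MAP order.
#' @export
asymptotic_map_order <- function(alpha, gamma, t, entropy_curve,
                                 r_max = length(entropy_curve) - 1L,
                                 alphabet_size = 2L) {
  stopifnot(t >= 0, length(entropy_curve) >= r_max + 1L)
  A <- alphabet_size
  orders <- 0:r_max
  score <- -(A - 1) * A^orders * gamma +
    A^orders * (lgamma(A * alpha) - A * lgamma(alpha)) -
    t * entropy_curve[orders + 1L]
  orders[which.max(score)]
}
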