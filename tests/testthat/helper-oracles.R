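# Quadrature oracles for the Dirichlet-multinomial machinery (binary
# alphabet). These integrate over the emission parameter theta directly and
# are independent of the log-gamma implementation they check.

# log integral over theta of the beta-discounted likelihood of one context
# with counts (n0, n1), under a symmetric Dirichlet(alpha) prior.
oracle_context_log_evidence <- function(n0, n1, alpha, beta) {
  f <- function(th) th^(beta * n1 + alpha - 1) * (1 - th)^(beta * n0 + alpha - 1)
  num <- stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  log(num) - lbeta(alpha, alpha)
}

# log evidence of a whole binary sequence at order R in {0, 1}: product of
# the independent per-context integrals.
oracle_log_evidence <- function(x, R, alpha, beta) {
  cc <- count_contexts(x, R)
  m <- cc$ncs[[R + 1L]]
  total <- 0
  for (i in seq_len(nrow(m))) {
    if (sum(m[i, ]) == 0 || beta == 0) next
    total <- total + oracle_context_log_evidence(m[i, 1], m[i, 2],
                                                 alpha, beta)
  }
  total
}

# posterior mean of theta_1 for one context under beta-discounted counts,
# by quadrature.
oracle_posterior_mean1 <- function(n0, n1, alpha, beta) {
  f <- function(th) th^(beta * n1 + alpha - 1) * (1 - th)^(beta * n0 + alpha - 1)
  num <- stats::integrate(function(th) th * f(th), 0, 1, rel.tol = 1e-12)$value
  den <- stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  num / den
}

# prior-weighted mixture of per-order posterior-mean predictives for
# symbol 1, by quadrature; r_max <= length(history).
oracle_predictive_average1 <- function(x, history, alpha, beta, gamma,
                                       r_max) {
  cc <- count_contexts(x, r_max)
  w <- exp(-gamma * 1 * 2^(0:r_max))
  terms <- vapply(0:r_max, function(R) {
    m <- cc$ncs[[R + 1L]]
    ctx <- if (R == 0L) "" else
      paste(utils::tail(history, R), collapse = "")
    row <- if (R == 0L) 1L else match(ctx, rownames(m))
    oracle_posterior_mean1(m[row, 1], m[row, 2], alpha, beta)
  }, numeric(1))
  sum(w * terms) / sum(w)
}

# all binary sequences of length t as a list of integer vectors
all_binary_seqs <- function(t) {
  if (t == 0L) return(list(integer(0)))
  lapply(0:(2^t - 1L), function(v) as.integer(intToBits(v)[1:t]))
}

# deterministic period-2 alternator as an order-1 model
alternator_model <- function() {
  markov_model(1L, matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
}
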