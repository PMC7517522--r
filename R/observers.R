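#' Specify an observer strategy
#'
#' An observer is a prediction strategy plus its parameters. The two Bayesian
#' n-gram strategies are parameterized by the Dirichlet concentration
#' `alpha`, the data-use weight `beta` (counts enter the observer's internal
#' model as `beta * n`), and the complexity penalty `gamma` on higher Markov
#' orders. The GLM strategy predicts the next symbol through a
#' ridge-penalized logistic regression on the raw values of the last
#' `window` symbols.
#'
#' @param strategy One of `"ngram_argmax"`, `"ngram_average"`, `"glm"`.
#' @param alpha Concentration, `> 0` (`>= 1` for `ngram_argmax`, where the
#'   predictive is a Dirichlet mode).
#' @param beta Data-use weight in `[0, 1]`.
#' @param gamma Complexity penalty, `>= 0`.
#' @param window GLM history length `k >= 1`.
#' @param ridge GLM L2 penalty (handles perfectly separable histories).
#' @return An object of class `"observer_spec"`.
#' @export
observer_spec <- function(strategy = c("ngram_argmax", "ngram_average", "glm"),
                          alpha = 1, beta = 1, gamma = 1,
                          window = 1L, ridge = 1e-4) {
  strategy <- match.arg(strategy)
  if (strategy == "glm") {
    if (window < 1) stop("window must be >= 1")
    out <- list(strategy = strategy, window = as.integer(window),
                ridge = ridge)
  } else {
    if (alpha <= 0) stop("alpha must be positive")
    if (strategy == "ngram_argmax" && alpha < 1)
      stop("ngram_argmax requires alpha >= 1")
    if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
    if (gamma < 0) stop("gamma must be >= 0")
    out <- list(strategy = strategy, alpha = alpha, beta = beta,
                gamma = gamma)
  }
  structure(out, class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  if (x$strategy == "glm")
    cat(sprintf("observer: glm (k=%d, ridge=%g)\n", x$window, x$ridge))
  else
    cat(sprintf("observer: %s (alpha=%g, beta=%g, gamma=%g)\n",
                x$strategy, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Per-trial emission probabilities of an observer
#'
#' The deterministic fingerprint of a strategy on a stimulus: for each trial
#' `t`, the probability vector over the next symbol that the observer's
#' strategy assigns given the stimulus history `s_1..s_{t-1}` (the prediction
#' for trial `t` is made before `s_t` is shown; trial 1 is uniform for every
#' strategy). Bayesian strategies truncate orders at `min(r_max, t - 1)`, the
#' orders whose contexts have been realized.
#'
#' @param spec An [observer_spec()].
#' @param stimulus Integer 0-based symbol sequence.
#' @param r_max Truncation order for the Bayesian strategies (default 8).
#' @param A Alphabet size (GLM supports 2 only).
#' @param trace Optional precomputed internal count trace (recycled across
#'   grid evaluations on the same stimulus).
#' @return A `"prediction_trace"` object whose `emission_probs` is a
#'   `length(stimulus) x A` matrix of per-trial probabilities; `predictions`
#'   is `NULL` until guesses are drawn (see [simulate_observer()]).
#' @export
emission_stream <- function(spec, stimulus, r_max = 8L, A = 2L,
                            trace = NULL) {
  stopifnot(inherits(spec, "observer_spec"))
  stimulus <- check_sequence(stimulus, A)
  if (spec$strategy == "glm") {
    if (A != 2L) stop("the GLM strategy supports binary alphabets only")
    p <- stream_glm(stimulus, spec$window, spec$ridge)
  } else {
    if (is.null(trace)) trace <- count_trace(stimulus, r_max, A)
    p <- switch(spec$strategy,
      ngram_argmax = stream_ngram_argmax(trace, spec$alpha, spec$beta,
                                         spec$gamma),
      ngram_average = stream_ngram_average(trace, spec$alpha, spec$beta,
                                           spec$gamma))
  }
  prediction_trace(stimulus, emission_probs = p, spec = spec, r_max = r_max)
}

# Reference emission stream: a per-trial loop through count_contexts() and
# the scalar predictive functions. Slow, but independent of the incremental
# count-trace fast path; used to validate it and to freeze fixtures.
emission_stream_reference <- function(spec, stimulus, r_max = 8L, A = 2L) {
  stopifnot(inherits(spec, "observer_spec"))
  ab <- if (A == 2L) binary_alphabet() else
    alphabet(as.character(0:(A - 1L)))
  N <- length(stimulus)
  p <- matrix(1 / A, N, A)
  for (t in seq_len(N)) {
    if (t == 1L) next
    hist <- stimulus[seq_len(t - 1L)]
    r_t <- min(r_max, t - 1L)
    if (spec$strategy == "glm") {
      p[t, ] <- fit_glm_step(hist, spec$window, spec$ridge)
      next
    }
    counts <- count_contexts(hist, r_t, ab)
    if (spec$strategy == "ngram_argmax") {
      post <- order_posterior(counts, spec$alpha, spec$beta, spec$gamma, r_t)
      ctx <- if (post$map_order == 0L) "" else
        paste(ab$symbols[utils::tail(hist, post$map_order) + 1L],
              collapse = "")
      p[t, ] <- vapply(0:(A - 1L), function(s)
        predictive_argmax(counts, spec$alpha, spec$beta, post$map_order,
                          ctx, s), numeric(1))
    } else {
      p[t, ] <- vapply(0:(A - 1L), function(s)
        predictive_average(counts, spec$alpha, spec$beta, spec$gamma,
                           r_t, hist, s), numeric(1))
    }
  }
  prediction_trace(stimulus, emission_probs = p, spec = spec, r_max = r_max)
}

# Constructor for prediction traces.
prediction_trace <- function(stimulus, emission_probs, spec = NULL,
                             r_max = NA_integer_, predictions = NULL) {
  emission_probs <- as.matrix(emission_probs)
  if (nrow(emission_probs) != length(stimulus))
    stop("emission_probs must have one row per trial")
  if (nrow(emission_probs) &&
      any(abs(rowSums(emission_probs) - 1) > 1e-10))
    stop("each emission row must sum to 1 (within 1e-10)")
  structure(list(stimulus = as.integer(stimulus),
                 emission_probs = emission_probs,
                 predictions = if (!is.null(predictions))
                   as.integer(predictions),
                 spec = spec, r_max = r_max),
            class = "prediction_trace")
}

#' @export
print.prediction_trace <- function(x, ...) {
  cat(sprintf("prediction trace: %d trials%s\n", length(x$stimulus),
              if (is.null(x$predictions)) " (emission probabilities only)"
              else ""))
  if (!is.null(x$spec)) print(x$spec)
  invisible(x)
}

#' Draw a probability-matched guess
#'
#' Probability matching: the observer guesses symbol `s` with probability
#' equal to its estimated emission probability `q(s)` (rather than always
#' guessing the mode).
#'
#' @param emission Probability vector over symbols (must sum to 1 within
#'   1e-10), or a matrix with one row per trial.
#' @return 0-based guessed symbol(s), one per row. Uses the current RNG
#'   state; seed with [set.seed()] or [with_seed] wrappers for
#'   reproducibility.
#' @export
probability_match <- function(emission) {
  if (is.null(dim(emission))) emission <- matrix(emission, nrow = 1L)
  if (any(emission < 0) || any(abs(rowSums(emission) - 1) > 1e-10))
    stop("emission rows must be probability vectors summing to 1")
  cum <- t(apply(emission, 1L, cumsum))
  u <- stats::runif(nrow(emission))
  guess <- rowSums(u > cum)              # index of the interval u falls in
  as.integer(pmin(guess, ncol(emission) - 1L))
}

#' One step of the GLM observer's fit
#'
#' Builds every (length-k window, next symbol) pair available in `history`,
#' fits an intercept plus k-weight logistic regression by ridge-penalized
#' maximum likelihood, and returns the predicted probability vector for the
#' symbol following the final window. Returns the uniform vector until at
#' least `k + 2` training pairs exist.
#'
#' @param history Integer 0/1 sequence observed so far.
#' @param window History length `k >= 1`.
#' @param ridge L2 penalty on the non-intercept weights.
#' @return Length-2 probability vector `(p(0), p(1))`.
#' @export
fit_glm_step <- function(history, window, ridge = 1e-4) {
  k <- as.integer(window)
  if (k < 1L) stop("window must be >= 1")
  n <- length(history)
  n_pairs <- n - k
  if (n_pairs < k + 2L) return(c(0.5, 0.5))
  X <- matrix(0, n_pairs, k)
  for (j in seq_len(k)) X[, j] <- history[(k + 1L):n - j]
  y <- history[(k + 1L):n]
  coef <- ridge_logistic(X, y, lambda = ridge)
  win <- history[n + 1L - seq_len(k)]
  p1 <- stats::plogis(coef[1L] + sum(coef[-1L] * win))
  c(1 - p1, p1)
}

#' Simulate a probability-matching observer
#'
#' Runs the strategy's emission stream over the stimulus and draws one
#' probability-matched guess per trial. In `"discount"` mode (the default)
#' the observer's counts are the full history discounted by `beta`, exactly
#' matching the likelihood formulas used for inference. In `"stochastic"`
#' mode each observation is independently dropped from the observer's counts
#' with probability `1 - beta` (and the emission formulas then use the raw
#' retained counts); this models the dropping literally but does not match
#' the discounted likelihood exactly.
#'
#' @inheritParams emission_stream
#' @param seed Integer seed for the guess draws (and the dropout draws in
#'   stochastic mode).
#' @param dropout_mode `"discount"` or `"stochastic"`.
#' @return A `"prediction_trace"` with both `emission_probs` and
#'   `predictions`.
#' @export
simulate_observer <- function(spec, stimulus, seed = 1L, r_max = 8L, A = 2L,
                              dropout_mode = c("discount", "stochastic")) {
  dropout_mode <- match.arg(dropout_mode)
  stimulus <- check_sequence(stimulus, A)
  with_seed(seed, {
    if (dropout_mode == "stochastic" && spec$strategy != "glm") {
      retain <- as.numeric(stats::runif(length(stimulus)) < spec$beta)
      tr <- count_trace(stimulus, r_max, A, retain = retain)
      p <- switch(spec$strategy,
        ngram_argmax = stream_ngram_argmax(tr, spec$alpha, 1, spec$gamma),
        ngram_average = stream_ngram_average(tr, spec$alpha, 1, spec$gamma))
      trace <- prediction_trace(stimulus, p, spec = spec, r_max = r_max)
    } else {
      trace <- emission_stream(spec, stimulus, r_max = r_max, A = A)
    }
    trace$predictions <- probability_match(trace$emission_probs)
    trace
  })
}

#' Simulate an ensemble of identical observers ("clones")
#'
#' `n_clones` independent probability-matching runs of the same observer on
#' the same stimulus. The per-trial guess frequencies across clones estimate
#' the analytic emission stream; as the number of clones grows the average
#' prediction log-likelihood approaches the cross-entropy limit (see
#' [avg_loglik_infinite()]).
#'
#' @inheritParams simulate_observer
#' @param n_clones Number of identical observers, `>= 1`.
#' @return An `"ensemble_trace"`: list with the shared `stimulus`,
#'   `emission_probs`, the `n_clones x t` `prediction_matrix`, and per-trial
#'   `empirical_freqs` (t x A).
#' @export
run_ensemble <- function(spec, stimulus, n_clones, seed = 1L, r_max = 8L,
                         A = 2L) {
  if (n_clones < 1) stop("n_clones must be >= 1")
  stimulus <- check_sequence(stimulus, A)
  trace <- emission_stream(spec, stimulus, r_max = r_max, A = A)
  seeds <- derive_seeds(seed, n_clones)
  N <- length(stimulus)
  pred <- matrix(NA_integer_, n_clones, N)
  for (i in seq_len(n_clones))
    pred[i, ] <- with_seed(seeds[i], probability_match(trace$emission_probs))
  freqs <- matrix(0, N, A)
  for (s in 0:(A - 1L)) freqs[, s + 1L] <- colMeans(pred == s)
  structure(list(stimulus = stimulus, spec = spec, n_clones = n_clones,
                 emission_probs = trace$emission_probs,
                 prediction_matrix = pred, empirical_freqs = freqs),
            class = "ensemble_trace")
}

#' @export
print.ensemble_trace <- function(x, ...) {
  cat(sprintf("ensemble trace: %d clones x %d trials\n", x$n_clones,
              length(x$stimulus)))
  print(x$spec)
  invisible(x)
}
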