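# Sum of log emission probabilities at the observed predictions; -Inf when
# the candidate assigns probability zero to a realized guess, with the
# offending trials flagged in an attribute.
loglik_from_stream <- function(emission_probs, predictions) {
  N <- nrow(emission_probs)
  if (length(predictions) != N)
    stop("predictions must align with the stimulus (one guess per trial)")
  if (N == 0L) return(0)
  p <- emission_probs[cbind(seq_len(N), predictions + 1L)]
  zero <- which(p <= 0)
  ll <- if (length(zero)) -Inf else sum(log(p))
  if (length(zero)) attr(ll, "zero_prob_trials") <- zero
  ll
}

as_predictions <- function(predictions) {
  if (inherits(predictions, "prediction_trace")) {
    if (is.null(predictions$predictions))
      stop("prediction trace carries no guesses; run simulate_observer()")
    predictions$predictions
  } else as.integer(predictions)
}

#' Log-likelihood of a prediction stream under a candidate strategy
#'
#' The candidate's emission stream is a deterministic function of the
#' stimulus alone; the observer's guesses enter only through which per-trial
#' probability is scored. At each trial `t` the candidate's probability of
#' the observed guess (given `s_1..s_{t-1}`) contributes its log; trial 1
#' contributes `log(1/|A|)`. For `ngram_argmax` the MAP order `R*` is
#' recomputed each trial from strictly causal counts.
#'
#' @param stimulus Integer 0-based stimulus sequence.
#' @param predictions Integer guesses aligned to the stimulus, or a
#'   `"prediction_trace"` from [simulate_observer()].
#' @param spec The candidate [observer_spec()].
#' @param r_max Order truncation for n-gram candidates.
#' @param A Alphabet size.
#' @param trace Optional precomputed count trace for the stimulus.
#' @return The log-likelihood (`<= 0`; `-Inf` with a `zero_prob_trials`
#'   attribute if the candidate assigns probability 0 to a realized guess).
#' @export
loglik_observer <- function(stimulus, predictions, spec, r_max = 8L, A = 2L,
                            trace = NULL) {
  est <- emission_stream(spec, stimulus, r_max = r_max, A = A, trace = trace)
  loglik_from_stream(est$emission_probs, as_predictions(predictions))
}

#' @describeIn loglik_observer n-gram argmax candidate with parameters
#'   `alpha`, `beta`, `gamma`.
#' @param alpha,beta,gamma n-gram candidate parameters.
#' @export
loglik_ngram_argmax <- function(stimulus, predictions, alpha, beta, gamma,
                                r_max = 8L, A = 2L, trace = NULL) {
  spec <- observer_spec("ngram_argmax", alpha = alpha, beta = beta,
                        gamma = gamma)
  loglik_observer(stimulus, predictions, spec, r_max, A, trace)
}

#' @describeIn loglik_observer n-gram average candidate.
#' @export
loglik_ngram_average <- function(stimulus, predictions, alpha, beta, gamma,
                                 r_max = 8L, A = 2L, trace = NULL) {
  spec <- observer_spec("ngram_average", alpha = alpha, beta = beta,
                        gamma = gamma)
  loglik_observer(stimulus, predictions, spec, r_max, A, trace)
}

#' @describeIn loglik_observer GLM candidate with history length `window`.
#' @param window GLM history length.
#' @param ridge GLM L2 penalty.
#' @export
loglik_glm <- function(stimulus, predictions, window, ridge = 1e-4,
                       A = 2L) {
  spec <- observer_spec("glm", window = window, ridge = ridge)
  loglik_observer(stimulus, predictions, spec, A = A)
}

#' Average log-likelihood in the infinite-clone limit
#'
#' With arbitrarily many identical observers, the per-trial average
#' log-likelihood of a candidate becomes a cross-entropy between the true
#' observer's emission probabilities and the candidate's:
#' `sum_t sum_s p_obs(s | h_t) log p_model(s | h_t)`. By Gibbs' inequality
#' it is maximized exactly when the candidate's emission stream matches
#' `p_obs` trial by trial.
#'
#' @param p_obs `t x A` matrix of the true observer's per-trial emission
#'   probabilities (or a `"prediction_trace"`).
#' @param spec Candidate [observer_spec()].
#' @inheritParams loglik_observer
#' @return Total cross-entropy score (`<= 0`; `-Inf`, flagged, when the
#'   candidate puts probability 0 where `p_obs > 0`).
#' @export
avg_loglik_infinite <- function(p_obs, spec, stimulus, r_max = 8L, A = 2L,
                                trace = NULL) {
  if (inherits(p_obs, "prediction_trace")) p_obs <- p_obs$emission_probs
  p_obs <- as.matrix(p_obs)
  if (nrow(p_obs) != length(stimulus))
    stop("p_obs must have one row per trial")
  est <- emission_stream(spec, stimulus, r_max = r_max, A = A, trace = trace)
  pm <- est$emission_probs
  bad <- p_obs > 0 & pm <= 0
  if (any(bad)) {
    ll <- -Inf
    attr(ll, "zero_prob_trials") <- unique(which(bad, arr.ind = TRUE)[, 1L])
    return(ll)
  }
  lp <- ifelse(p_obs > 0, log(pmax(pm, .Machine$double.xmin)), 0)
  sum(p_obs * lp)
}

#' Identifiability ratio of an n-gram strategy
#'
#' Individual n-gram parameters are determined only up to a multiplicative
#' constant; the identifiable combination is `phi = beta / (alpha - 1)` for
#' `ngram_argmax` (undefined at `alpha = 1`) and `phi = beta / alpha` for
#' `ngram_average`.
#'
#' @param spec An n-gram [observer_spec()].
#' @return The phi ratio.
#' @export
phi_ratio <- function(spec) {
  stopifnot(inherits(spec, "observer_spec"))
  switch(spec$strategy,
    ngram_argmax = {
      if (spec$alpha == 1)
        stop("phi is undefined for ngram_argmax at alpha = 1")
      spec$beta / (spec$alpha - 1)
    },
    ngram_average = spec$beta / spec$alpha,
    stop("phi is defined for n-gram strategies only"))
}

# phi at a grid point, NA where undefined.
phi_at <- function(strategy, alpha, beta) {
  if (strategy == "ngram_average") return(beta / alpha)
  ifelse(alpha == 1, NA_real_, beta / (alpha - 1))
}

#' Grid-search maximum likelihood over a strategy's parameters
#'
#' Evaluates the strategy's log-likelihood at every point of a parameter
#' grid (the likelihood surfaces carry ridges that defeat continuous
#' optimizers, so the search is exhaustive and deterministic). Multiple
#' global maxima are first class: every point within `tol` of the maximum is
#' kept, and the identifiable quantities are reported as intervals over that
#' argmax set, mirroring the lower/upper-bound protocol.
#'
#' @param stimulus Integer 0-based stimulus sequence.
#' @param evidence Either observed predictions (integer vector or
#'   `"prediction_trace"`) scored by [loglik_observer()], or a `t x A`
#'   emission-probability matrix (the infinite-clone evidence) scored by
#'   [avg_loglik_infinite()].
#' @param strategy `"ngram_argmax"`, `"ngram_average"` or `"glm"`.
#' @param grid Named list of parameter value vectors: `alpha`, `beta`,
#'   `gamma` for n-gram strategies; `window` for the GLM.
#' @param tol Points within `tol` of the maximum join the argmax set.
#' @param ridge GLM L2 penalty.
#' @inheritParams loglik_observer
#' @return An object of class `"mle_result"`: `strategy`, `log_lik_max`,
#'   the evaluated `grid` (with a `loglik` column), `argmax_set`,
#'   `phi_lower`/`phi_upper`, `gamma_range` (n-gram) or `k_range` (GLM).
#' @export
grid_search <- function(stimulus, evidence, strategy, grid, tol = 1e-9,
                        r_max = 8L, A = 2L, ridge = 1e-4) {
  strategy <- match.arg(strategy, c("ngram_argmax", "ngram_average", "glm"))
  infinite <- is.matrix(evidence) ||
    (inherits(evidence, "prediction_trace") && is.null(evidence$predictions))
  score <- function(spec, trace) {
    if (infinite) avg_loglik_infinite(evidence, spec, stimulus, r_max, A,
                                      trace)
    else loglik_observer(stimulus, as_predictions(evidence), spec, r_max, A,
                         trace)
  }
  if (strategy == "glm") {
    if (is.null(grid$window)) stop("GLM grid needs a 'window' component")
    pts <- data.frame(window = as.integer(grid$window))
    ll <- vapply(seq_len(nrow(pts)), function(i)
      as.numeric(score(observer_spec("glm", window = pts$window[i],
                                     ridge = ridge), NULL)), numeric(1))
  } else {
    need <- c("alpha", "beta", "gamma")
    if (!all(need %in% names(grid)))
      stop("n-gram grid needs alpha, beta and gamma components")
    pts <- expand.grid(alpha = grid$alpha, beta = grid$beta,
                       gamma = grid$gamma, KEEP.OUT.ATTRS = FALSE)
    trace <- count_trace(check_sequence(stimulus, A), r_max, A)
    ll <- vapply(seq_len(nrow(pts)), function(i)
      as.numeric(score(observer_spec(strategy, alpha = pts$alpha[i],
                                     beta = pts$beta[i],
                                     gamma = pts$gamma[i]), trace)),
      numeric(1))
  }
  if (all(!is.finite(ll)))
    stop("every grid point has log-likelihood -Inf")
  pts$loglik <- ll
  mx <- max(ll)
  amax <- which(ll >= mx - tol)
  res <- list(strategy = strategy, log_lik_max = mx, grid = pts,
              argmax_set = pts[amax, , drop = FALSE])
  if (strategy == "glm") {
    res$k_range <- range(pts$window[amax])
    res$phi_lower <- res$phi_upper <- NA_real_
    res$gamma_range <- c(NA_real_, NA_real_)
  } else {
    phi <- phi_at(strategy, pts$alpha[amax], pts$beta[amax])
    res$phi_lower <- if (all(is.na(phi))) NA_real_ else min(phi, na.rm = TRUE)
    res$phi_upper <- if (all(is.na(phi))) NA_real_ else max(phi, na.rm = TRUE)
    res$gamma_range <- range(pts$gamma[amax])
  }
  structure(res, class = "mle_result")
}

#' @export
print.mle_result <- function(x, ...) {
  cat(sprintf("grid-search MLE for %s: max log-likelihood %.4f at %d point(s)\n",
              x$strategy, x$log_lik_max, nrow(x$argmax_set)))
  if (x$strategy == "glm")
    cat(sprintf("  k in [%d, %d]\n", x$k_range[1], x$k_range[2]))
  else
    cat(sprintf("  phi in [%s, %s], gamma in [%g, %g]\n",
                format(x$phi_lower), format(x$phi_upper),
                x$gamma_range[1], x$gamma_range[2]))
  invisible(x)
}

#' Default candidate grids for strategy classification
#'
#' Coarse grids over the n-gram parameters and the GLM history length used
#' by [classify_strategy()] and the experiments when none are supplied.
#'
#' @return Named list of per-strategy grids.
#' @export
default_grids <- function() {
  ngram <- list(alpha = c(1, 2, 3), beta = c(0.5, 1), gamma = c(0.5, 2))
  list(ngram_argmax = ngram, ngram_average = ngram,
       glm = list(window = 1:3))
}

#' Classify an observer's strategy by maximum likelihood
#'
#' Grid-search maximizes each candidate strategy's likelihood of the
#' prediction stream and returns the strategy with the largest maximized
#' log-likelihood, plus the coarse class label that merges the two n-gram
#' strategies into "Bayesian". Ties break Bayesian-first (argmax, then
#' average, then GLM).
#'
#' @inheritParams grid_search
#' @param predictions Observed guesses (integer vector or
#'   `"prediction_trace"`), or an emission-probability matrix for
#'   infinite-clone evidence.
#' @param grids Per-strategy grids as from [default_grids()].
#' @return List with `label` (winning strategy), `coarse` (`"Bayesian"` or
#'   `"GLM"`), `log_liks`, and per-strategy `results`.
#' @export
classify_strategy <- function(stimulus, predictions, grids = default_grids(),
                              tol = 1e-9, r_max = 8L, A = 2L,
                              ridge = 1e-4) {
  if (length(grids) < 2L) stop("need at least two candidate strategies")
  order_pref <- intersect(c("ngram_argmax", "ngram_average", "glm"),
                          names(grids))
  results <- lapply(order_pref, function(st)
    grid_search(stimulus, predictions, st, grids[[st]], tol = tol,
                r_max = r_max, A = A, ridge = ridge))
  names(results) <- order_pref
  lls <- vapply(results, `[[`, numeric(1), "log_lik_max")
  label <- order_pref[which.max(lls)]   # first max: Bayesian-first ties
  list(label = label,
       coarse = if (label == "glm") "GLM" else "Bayesian",
       log_liks = lls, results = results)
}
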