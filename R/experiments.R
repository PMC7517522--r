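#' Strategy-class confusion experiment
#'
#' Simulates a cohort of probability-matching observers — half Bayesian
#' (n-gram), half GLM — each seeing its own order-R Markov stimulus, and
#' classifies every observer's single prediction string with
#' [classify_strategy()]. The tally of inferred versus actual class is the
#' model-recovery confusion matrix; perfect recovery is a diagonal matrix.
#'
#' Defaults: each observer gets a fresh model sampled with symmetric
#' Dirichlet(`concentration`) emission rows and a fresh stimulus; Bayesian
#' observers are `ngram_average` with `alpha = 1` and `(beta, gamma)` cycling
#' over `{0.5, 1} x {0.5, 2}`; GLM observers cycle `window` over `1:3`. All
#' draws derive from the single `seed`.
#'
#' @param n_per_class Observers per class (0 gives an empty tally).
#' @param stimulus_order Markov order of the generated stimuli.
#' @param n_trials Stimulus length per observer.
#' @param grids Candidate grids for [classify_strategy()].
#' @param seed Master seed.
#' @param bayes_specs,glm_specs Optional lists of [observer_spec()]s cycled
#'   over the observers of each class.
#' @param r_max Order truncation for n-gram candidates.
#' @param concentration Dirichlet concentration for stimulus models.
#' @return An object of class `"confusion_matrix"`: the 2 x 2 `table`
#'   (inferred x actual), plus a per-observer `details` data frame and the
#'   configuration.
#' @export
confusion_experiment <- function(n_per_class = 20L, stimulus_order = 2L,
                                 n_trials = 500L, grids = default_grids(),
                                 seed = 1L, bayes_specs = NULL,
                                 glm_specs = NULL, r_max = 8L,
                                 concentration = 1) {
  if (is.null(bayes_specs)) {
    pg <- expand.grid(beta = c(0.5, 1), gamma = c(0.5, 2))
    bayes_specs <- lapply(seq_len(nrow(pg)), function(i)
      observer_spec("ngram_average", alpha = 1, beta = pg$beta[i],
                    gamma = pg$gamma[i]))
  }
  if (is.null(glm_specs))
    glm_specs <- lapply(1:3, function(k) observer_spec("glm", window = k))
  classes <- c("Bayesian", "GLM")
  tab <- matrix(0L, 2L, 2L, dimnames = list(inferred = classes,
                                            actual = classes))
  details <- NULL
  if (n_per_class > 0L) {
    n_obs <- 2L * n_per_class
    seeds <- matrix(derive_seeds(seed, 3L * n_obs), ncol = 3L)
    rows <- vector("list", n_obs)
    for (i in seq_len(n_obs)) {
      actual <- classes[((i - 1L) %/% n_per_class) + 1L]
      j <- ((i - 1L) %% n_per_class) + 1L
      spec <- if (actual == "Bayesian")
        bayes_specs[[(j - 1L) %% length(bayes_specs) + 1L]]
      else glm_specs[[(j - 1L) %% length(glm_specs) + 1L]]
      model <- sample_markov_model(stimulus_order,
                                   concentration = concentration,
                                   seed = seeds[i, 1L])
      stim <- generate_stimulus(model, n_trials, seed = seeds[i, 2L])
      trace <- simulate_observer(spec, stim, seed = seeds[i, 3L],
                                 r_max = r_max)
      cls <- classify_strategy(stim, trace$predictions, grids,
                               r_max = r_max)
      tab[cls$coarse, actual] <- tab[cls$coarse, actual] + 1L
      rows[[i]] <- data.frame(observer = i, actual = actual,
                              inferred = cls$coarse, label = cls$label,
                              true_strategy = spec$strategy,
                              loglik_best = max(cls$log_liks))
    }
    details <- do.call(rbind, rows)
  }
  structure(list(table = tab, details = details,
                 config = list(n_per_class = n_per_class,
                               stimulus_order = stimulus_order,
                               n_trials = n_trials, seed = seed,
                               r_max = r_max,
                               concentration = concentration)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  tab <- x$table
  out <- cbind(tab, Total = rowSums(tab))
  out <- rbind(out, Total = colSums(out))
  cat("confusion matrix (inferred x actual):\n")
  print(out)
  invisible(x)
}

#' Parameter-recovery experiment with infinite-clone evidence
#'
#' For each combination of stimulus order `R` and prediction count `N`, and
#' each replicate: sample a stimulus, compute the true observer's analytic
#' emission stream (the infinite-clone evidence), grid-search the strategy's
#' likelihood, and record the absolute errors of the smallest and largest
#' inferred phi (and, for `ngram_average`, gamma) against the truth — the
#' lower-bound and upper-bound error protocol for likelihood surfaces with
#' non-unique maxima.
#'
#' @param strategy `"ngram_argmax"` or `"ngram_average"`.
#' @param true_specs An [observer_spec()] or list of them, cycled over
#'   replicates.
#' @param R_list,N_list Stimulus orders and prediction counts to cross.
#' @param grid Parameter grid searched (should contain the true phi).
#' @param replicates Replicates per `(R, N)` cell (0 gives empty tables).
#' @param seed Master seed.
#' @inheritParams confusion_experiment
#' @return List of class `"recovery_result"` with per-replicate `details`
#'   and a per-cell `summary` (mean errors with normal-approximation 95%
#'   confidence intervals).
#' @export
recovery_experiment <- function(strategy = "ngram_average", true_specs,
                                R_list = c(2L, 4L), N_list = c(100L, 500L),
                                grid = default_grids()[[strategy]],
                                replicates = 3L, seed = 1L, r_max = 8L,
                                concentration = 1) {
  strategy <- match.arg(strategy, c("ngram_argmax", "ngram_average"))
  if (inherits(true_specs, "observer_spec")) true_specs <- list(true_specs)
  cells <- expand.grid(R = R_list, N = N_list, rep = seq_len(replicates),
                       KEEP.OUT.ATTRS = FALSE)
  details <- NULL
  if (nrow(cells) > 0L && replicates > 0L) {
    seeds <- matrix(derive_seeds(seed, 2L * nrow(cells)), ncol = 2L)
    rows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      spec <- true_specs[[(cells$rep[i] - 1L) %% length(true_specs) + 1L]]
      model <- sample_markov_model(cells$R[i],
                                   concentration = concentration,
                                   seed = seeds[i, 1L])
      stim <- generate_stimulus(model, cells$N[i], seed = seeds[i, 2L])
      p_obs <- emission_stream(spec, stim, r_max = r_max)$emission_probs
      fit <- grid_search(stim, p_obs, strategy, grid, r_max = r_max)
      phi_true <- phi_ratio(spec)
      rows[[i]] <- data.frame(
        R = cells$R[i], N = cells$N[i], rep = cells$rep[i],
        phi_true = phi_true,
        phi_lower = fit$phi_lower, phi_upper = fit$phi_upper,
        err_lower = abs(fit$phi_lower - phi_true),
        err_upper = abs(fit$phi_upper - phi_true),
        gamma_true = spec$gamma,
        gamma_err_lower = if (strategy == "ngram_average")
          abs(fit$gamma_range[1] - spec$gamma) else NA_real_,
        gamma_err_upper = if (strategy == "ngram_average")
          abs(fit$gamma_range[2] - spec$gamma) else NA_real_)
    }
    details <- do.call(rbind, rows)
  }
  summary <- NULL
  if (!is.null(details)) {
    ci <- function(v) {
      m <- mean(v)
      half <- if (length(v) > 1L) 1.96 * stats::sd(v) / sqrt(length(v)) else 0
      c(mean = m, lo = m - half, hi = m + half)
    }
    parts <- split(details, interaction(details$R, details$N, drop = TRUE))
    summary <- do.call(rbind, lapply(parts, function(d) {
      lo <- ci(d$err_lower); hi <- ci(d$err_upper)
      data.frame(R = d$R[1], N = d$N[1], n = nrow(d),
                 err_lower_mean = lo["mean"], err_lower_ci_lo = lo["lo"],
                 err_lower_ci_hi = lo["hi"],
                 err_upper_mean = hi["mean"], err_upper_ci_lo = hi["lo"],
                 err_upper_ci_hi = hi["hi"], row.names = NULL)
    }))
    summary <- summary[order(summary$R, summary$N), , drop = FALSE]
  }
  structure(list(strategy = strategy, details = details, summary = summary,
                 config = list(R_list = R_list, N_list = N_list,
                               replicates = replicates, seed = seed,
                               grid = grid, r_max = r_max,
                               concentration = concentration)),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("phi recovery for %s (%d replicates per cell):\n",
              x$strategy, x$config$replicates))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
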