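test_that("prediction log-likelihoods match hand traces and stay nonpositive", {
  # stimulus "11", predictions "11", R* pinned at 0 by gamma:
  # trial 1 uniform, trial 2 gives (2+1-1)/(2+1)
  ll <- loglik_ngram_argmax(string_to_seq("11"), c(1L, 1L),
                            alpha = 2, beta = 1, gamma = 50, r_max = 2)
  expect_equal(as.numeric(ll), log(1 / 2) + log(2 / 3), tolerance = 1e-12)

  # beta = 0: every trial is the uniform prior predictive
  x <- with_seed(1, sample(0:1, 40, replace = TRUE))
  pred <- with_seed(2, sample(0:1, 40, replace = TRUE))
  for (st in c("ngram_argmax", "ngram_average")) {
    sp <- observer_spec(st, alpha = 1, beta = 0, gamma = 1)
    expect_equal(as.numeric(loglik_observer(x, pred, sp)), 40 * log(0.5),
                 tolerance = 1e-12)
  }

  # nonpositivity and monotonicity under concatenation for all strategies
  m <- sample_markov_model(1, seed = 9)
  x2 <- generate_stimulus(m, 60, seed = 10)
  tr <- simulate_observer(observer_spec("ngram_average", alpha = 1,
                                        beta = 1, gamma = 0.5), x2,
                          seed = 11)
  for (sp in list(observer_spec("ngram_argmax", alpha = 2, beta = 1,
                                gamma = 0.5),
                  observer_spec("ngram_average", alpha = 1, beta = 0.5,
                                gamma = 2),
                  observer_spec("glm", window = 2))) {
    lls <- vapply(c(20, 40, 60), function(tt)
      as.numeric(loglik_observer(x2[1:tt], tr$predictions[1:tt], sp)),
      numeric(1))
    expect_true(all(lls <= 0))
    expect_true(all(diff(lls) <= 1e-12))   # more trials, lower loglik
  }

  # a zero-probability guess is -Inf and flagged with its trials
  ones <- rep(1L, 30)
  bad <- c(rep(1L, 29), 0L)
  llz <- loglik_ngram_argmax(ones, bad, alpha = 1, beta = 1, gamma = 50,
                             r_max = 2)
  expect_identical(as.numeric(llz), -Inf)
  expect_identical(attr(llz, "zero_prob_trials"), 30L)
})

test_that("GLM log-likelihood uses log probabilities with a uniform fallback", {
  # data-starved: all trials in fallback
  short <- string_to_seq("0110")
  expect_equal(as.numeric(loglik_glm(short, c(1L, 0L, 1L, 0L), window = 3)),
               4 * log(0.5), tolerance = 1e-12)
  # alternating stimulus with matching predictions beats the fallback
  alt <- rep(c(0L, 1L), 25)
  # predictions that themselves continue the alternation
  ll <- as.numeric(loglik_glm(alt, alt, window = 1))
  expect_gt(ll, 50 * log(0.5))
  expect_lte(ll, 0)
})

test_that("the infinite-clone score is a cross-entropy maximized at the truth", {
  m <- sample_markov_model(1, seed = 30)
  x <- generate_stimulus(m, 80, seed = 31)
  truth <- observer_spec("ngram_average", alpha = 1, beta = 1, gamma = 0.5)
  p_obs <- emission_stream(truth, x)$emission_probs

  # candidate == truth recovers the negative total entropy of p_obs
  got <- avg_loglik_infinite(p_obs, truth, x)
  ent <- -sum(ifelse(p_obs > 0, p_obs * log(p_obs), 0))
  expect_equal(as.numeric(got), -ent, tolerance = 1e-10)

  # Gibbs: every mismatched candidate scores no higher, random instances
  cands <- list(observer_spec("ngram_average", alpha = 2, beta = 0.3,
                              gamma = 1),
                observer_spec("ngram_argmax", alpha = 2, beta = 1,
                              gamma = 0.5),
                observer_spec("glm", window = 2))
  for (s in 1:10) {
    xs <- generate_stimulus(m, 60, seed = 100 + s)
    ps <- emission_stream(truth, xs)$emission_probs
    base <- as.numeric(avg_loglik_infinite(ps, truth, xs))
    for (cand in cands)
      expect_lte(as.numeric(avg_loglik_infinite(ps, cand, xs)),
                 base + 1e-10)
  }

  # deterministic p_obs matched by a deterministic candidate scores 0
  # beyond the uniform first trial
  ones <- rep(1L, 10)
  det <- observer_spec("ngram_argmax", alpha = 1, beta = 1, gamma = 1)
  p_det <- emission_stream(det, ones)$emission_probs
  expect_equal(as.numeric(avg_loglik_infinite(p_det, det, ones)), -log(2),
               tolerance = 1e-10)   # only trial 1 is entropic
})

test_that("phi ratios encode the identifiable parameter combination", {
  expect_equal(phi_ratio(observer_spec("ngram_argmax", alpha = 3, beta = 1)),
               0.5)
  expect_equal(phi_ratio(observer_spec("ngram_average", alpha = 2,
                                       beta = 1)), 0.5)
  expect_error(phi_ratio(observer_spec("ngram_argmax", alpha = 1)),
               "undefined")
  expect_error(phi_ratio(observer_spec("glm", window = 2)), "n-gram")
})

test_that("grid search reports argmax sets, phi intervals and ray ties", {
  m <- sample_markov_model(2, seed = 40)
  x <- generate_stimulus(m, 150, seed = 41)
  truth <- observer_spec("ngram_average", alpha = 1, beta = 0.5,
                         gamma = 0.5)
  p_obs <- emission_stream(truth, x)$emission_probs

  # single-point grid
  g1 <- grid_search(x, p_obs, "ngram_average",
                    list(alpha = 1, beta = 0.5, gamma = 0.5))
  expect_equal(nrow(g1$argmax_set), 1L)
  expect_equal(g1$phi_lower, g1$phi_upper)

  # the rescaling ray (1, 0.5) ~ (2, 1) ties exactly; phi pinned at 0.5
  g2 <- grid_search(x, p_obs, "ngram_average",
                    list(alpha = c(1, 2), beta = c(0.5, 1),
                         gamma = c(0.5, 2)))
  amax <- g2$argmax_set
  expect_gte(nrow(amax), 2L)
  expect_true(all(amax$beta / amax$alpha == 0.5))
  expect_equal(c(g2$phi_lower, g2$phi_upper), c(0.5, 0.5))
  expect_equal(g2$gamma_range, c(0.5, 0.5))

  # evidence as observed guesses instead of probabilities
  trc <- simulate_observer(truth, x, seed = 42)
  g3 <- grid_search(x, trc, "ngram_average",
                    list(alpha = 1, beta = c(0.5, 1), gamma = 0.5))
  expect_s3_class(g3, "mle_result")
  expect_lte(g3$log_lik_max, 0)

  # every point -Inf is an error
  ones <- rep(1L, 20)
  bad_pred <- c(rep(1L, 19), 0L)
  expect_error(grid_search(ones, bad_pred, "ngram_argmax",
                           list(alpha = 1, beta = 1, gamma = 50)),
               "-Inf")
})

test_that("strategy classification picks the generating class", {
  m <- sample_markov_model(2, seed = 50)
  x <- generate_stimulus(m, 400, seed = 51)

  tr_b <- simulate_observer(observer_spec("ngram_average", alpha = 1,
                                          beta = 1, gamma = 0.5), x,
                            seed = 52)
  cls_b <- classify_strategy(x, tr_b$predictions)
  expect_equal(cls_b$coarse, "Bayesian")

  tr_g <- simulate_observer(observer_spec("glm", window = 3), x, seed = 53)
  cls_g <- classify_strategy(x, tr_g$predictions)
  expect_equal(cls_g$coarse, "GLM")

  # all-uniform streams tie every strategy; ties resolve Bayesian-first
  short <- string_to_seq("011")
  cls_t <- classify_strategy(short, c(0L, 1L, 1L),
                             grids = list(ngram_argmax = list(alpha = 1,
                                                              beta = 0,
                                                              gamma = 1),
                                          glm = list(window = 2)))
  expect_equal(cls_t$coarse, "Bayesian")
  expect_equal(unname(diff(cls_t$log_liks)), 0)
})

test_that("experiment harnesses handle degenerate configurations", {
  cm0 <- confusion_experiment(n_per_class = 0, seed = 1)
  expect_true(all(cm0$table == 0L))
  expect_null(cm0$details)

  rec0 <- recovery_experiment("ngram_average",
                              observer_spec("ngram_average", alpha = 1,
                                            beta = 0.5, gamma = 0.5),
                              R_list = 2L, N_list = 100L, replicates = 0L,
                              seed = 1)
  expect_null(rec0$details)

  # grid excluding the true phi: error at least the distance to the grid
  truth <- observer_spec("ngram_average", alpha = 1, beta = 0.5,
                         gamma = 0.5)
  rec <- recovery_experiment("ngram_average", truth, R_list = 2L,
                             N_list = 120L,
                             grid = list(alpha = 1, beta = 1,
                                         gamma = c(0.5, 2)),
                             replicates = 2L, seed = 3)
  expect_true(all(rec$details$err_lower >= 0.5 - 1e-12))  # |1 - 0.5|
})

test_that("small seeded confusion runs tally consistently and recover classes", {
  cm <- confusion_experiment(n_per_class = 3L, n_trials = 250L, seed = 17)
  # table and per-observer details agree, and columns sum to the cohort size
  expect_equal(unname(colSums(cm$table)), c(3L, 3L))
  expect_equal(sum(cm$table), nrow(cm$details))
  expect_equal(unname(cm$table["Bayesian", "Bayesian"]),
               sum(cm$details$actual == "Bayesian" &
                     cm$details$inferred == "Bayesian"))
  # classification is far above the 50% chance level (strategy-class
  # identifiability can genuinely fail for weakly structured stimuli, so
  # a perfect diagonal is not asserted at this scale)
  expect_gte(sum(diag(cm$table)), 4L)
  # same seed reproduces the experiment exactly
  cm2 <- confusion_experiment(n_per_class = 3L, n_trials = 250L, seed = 17)
  expect_identical(cm$table, cm2$table)
  expect_equal(cm$details, cm2$details)
})
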