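test_that("emission streams reproduce hand-traced probabilities", {
  # argmax with the prior pinning R* = 0: "1110", trial 4 sees n(1)=3, n=3
  es <- emission_stream(observer_spec("ngram_argmax", alpha = 2, beta = 1,
                                      gamma = 50),
                        string_to_seq("1110"), r_max = 4)
  expect_equal(es$emission_probs[4, 2], 4 / 5, tolerance = 1e-12)

  # trial 1 is uniform for every strategy
  x <- string_to_seq("10110")
  for (sp in list(observer_spec("ngram_argmax", alpha = 2),
                  observer_spec("ngram_average", alpha = 1),
                  observer_spec("glm", window = 2))) {
    p <- emission_stream(sp, x)$emission_probs
    expect_equal(p[1, ], c(0.5, 0.5))
    expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-10)
  }

  # average stream, trial 3 of "110": the 13/18 mixture
  es2 <- emission_stream(observer_spec("ngram_average", alpha = 1, beta = 1,
                                       gamma = log(2)),
                         string_to_seq("110"), r_max = 1)
  expect_equal(es2$emission_probs[3, 2], 13 / 18, tolerance = 1e-12)

  # deterministic function of (spec, stimulus): repeated calls agree exactly
  sp <- observer_spec("ngram_average", alpha = 1.5, beta = 0.7, gamma = 0.4)
  x2 <- with_seed(3, sample(0:1, 80, replace = TRUE))
  expect_identical(emission_stream(sp, x2)$emission_probs,
                   emission_stream(sp, x2)$emission_probs)
})

test_that("the incremental fast path equals the per-trial reference path", {
  m <- sample_markov_model(2, seed = 7)
  for (s in 1:3) {
    x <- generate_stimulus(m, 60, seed = s)
    for (sp in list(observer_spec("ngram_argmax", alpha = 2, beta = 0.7,
                                  gamma = 0.3),
                    observer_spec("ngram_argmax", alpha = 1, beta = 1,
                                  gamma = 1),
                    observer_spec("ngram_average", alpha = 1.5, beta = 0.5,
                                  gamma = 0.8),
                    observer_spec("glm", window = 2))) {
      fast <- emission_stream(sp, x, r_max = 4)$emission_probs
      ref <- predstrat:::emission_stream_reference(sp, x,
                                                   r_max = 4)$emission_probs
      expect_lt(max(abs(fast - ref)), 1e-9)
    }
  }
})

test_that("probability matching draws with the stated frequencies", {
  expect_identical(with_seed(1, probability_match(c(1, 0))), 0L)
  expect_identical(with_seed(1, probability_match(c(0, 1))), 1L)
  draws <- with_seed(5, probability_match(matrix(0.5, 1e5, 2)))
  expect_lt(abs(mean(draws) - 0.5), 4 * sqrt(0.25 / 1e5))
  # determinism under a fixed seed
  p <- matrix(c(0.3, 0.7), 50, 2, byrow = TRUE)
  expect_identical(with_seed(9, probability_match(p)),
                   with_seed(9, probability_match(p)))
  expect_error(probability_match(c(0.5, 0.6)), "sum")
})

test_that("the GLM step learns structure and falls back when data-starved", {
  expect_equal(fit_glm_step(c(0L, 1L, 0L), 1), c(0.5, 0.5))
  # 10+ perfectly alternating pairs: next symbol after 0 is (nearly) 1
  alt <- rep(c(0L, 1L), 6)
  p <- fit_glm_step(alt, 1)                     # last symbol is 1 -> next 0
  expect_gt(p[1], 0.9)
  p2 <- fit_glm_step(c(alt, 0L), 1)             # last symbol 0 -> next 1
  expect_gt(p2[2], 0.9)
  # intercept-dominated fit on an all-ones history
  expect_gt(fit_glm_step(rep(1L, 12), 2)[2], 0.9)
  # ridge-IRLS agrees with stats::glm on non-separable data at tiny penalty
  x <- with_seed(31, sample(0:1, 200, replace = TRUE))
  X <- cbind(x[1:198], x[2:199])                # two noisy regressors
  y <- with_seed(32, rbinom(198, 1, plogis(0.5 - X[, 1] + 0.8 * X[, 2])))
  b_ref <- unname(coef(glm(y ~ X, family = binomial())))
  b_got <- predstrat:::ridge_logistic(X, y, lambda = 1e-10)
  expect_equal(b_got, b_ref, tolerance = 1e-4)
})

test_that("simulated observers match their emission streams", {
  m <- sample_markov_model(1, seed = 4)
  x <- generate_stimulus(m, 100, seed = 5)

  # beta = 0 in discount mode: the prior predictive at every trial
  tr0 <- simulate_observer(observer_spec("ngram_average", alpha = 1,
                                         beta = 0, gamma = 1), x, seed = 1)
  expect_true(all(tr0$emission_probs == 0.5))

  # empirical-MLE convergence on a deterministic stimulus
  ones <- rep(1L, 200)
  tr1 <- simulate_observer(observer_spec("ngram_argmax", alpha = 1,
                                         beta = 1, gamma = 1), ones,
                           seed = 2)
  expect_equal(tr1$emission_probs[200, 2], 1, tolerance = 1e-9)
  expect_identical(tr1$predictions[150], 1L)

  # same seed, same trace; different seed, different guesses
  sp <- observer_spec("ngram_average", alpha = 1, beta = 1, gamma = 0.5)
  expect_identical(simulate_observer(sp, x, seed = 7)$predictions,
                   simulate_observer(sp, x, seed = 7)$predictions)
  expect_false(identical(simulate_observer(sp, x, seed = 7)$predictions,
                         simulate_observer(sp, x, seed = 8)$predictions))

  # stochastic dropout with beta = 1 retains everything: equals discounting
  tr_s <- simulate_observer(sp, x, seed = 7, dropout_mode = "stochastic")
  tr_d <- simulate_observer(sp, x, seed = 7)
  expect_equal(tr_s$emission_probs, tr_d$emission_probs, tolerance = 1e-12)
  # with beta < 1 the two dropout readings genuinely differ
  spd <- observer_spec("ngram_average", alpha = 1, beta = 0.5, gamma = 0.5)
  tr_s2 <- simulate_observer(spd, x, seed = 7, dropout_mode = "stochastic")
  tr_d2 <- simulate_observer(spd, x, seed = 7)
  expect_gt(max(abs(tr_s2$emission_probs - tr_d2$emission_probs)), 1e-4)
})

test_that("clone ensembles concentrate on the analytic emission stream", {
  m <- sample_markov_model(1, seed = 14)
  x <- generate_stimulus(m, 30, seed = 15)
  sp <- observer_spec("ngram_average", alpha = 1, beta = 1, gamma = 0.5)

  # a single clone is just one probability-matched trace
  e1 <- run_ensemble(sp, x, n_clones = 1, seed = 3)
  expect_identical(dim(e1$prediction_matrix), c(1L, 30L))
  expect_true(all(e1$empirical_freqs %in% c(0, 1)))

  # law of large numbers at 1e4 clones
  en <- run_ensemble(sp, x, n_clones = 1e4, seed = 3)
  p <- en$emission_probs[, 2]
  tol <- 4 * sqrt(pmax(p * (1 - p), 1e-12) / 1e4) + 1e-9
  share_ok <- mean(abs(en$empirical_freqs[, 2] - p) <= tol)
  expect_gte(share_ok, 0.99)

  # deterministic emission: all clones agree at that trial
  ones <- rep(1L, 20)
  ed <- run_ensemble(observer_spec("ngram_argmax", alpha = 1, beta = 1,
                                   gamma = 1), ones, n_clones = 50, seed = 4)
  expect_true(all(ed$prediction_matrix[, 20] == 1L))

  # adding clones never perturbs earlier clones' draws
  e5 <- run_ensemble(sp, x, n_clones = 5, seed = 3)
  expect_identical(e5$prediction_matrix,
                   en$prediction_matrix[1:5, , drop = FALSE])
})

test_that("a large complexity penalty collapses each stream to order 0", {
  m <- sample_markov_model(2, seed = 19)
  x <- generate_stimulus(m, 120, seed = 20)
  tr <- predstrat:::count_trace(x, 6, 2L)
  n1 <- tr$ncs[, 1, 2]; n <- tr$nc[, 1]

  # argmax at gamma = 200 (prior gap far beyond any evidence gap at t=120):
  # exactly the order-0 MAP predictive
  pa <- emission_stream(observer_spec("ngram_argmax", alpha = 2, beta = 1,
                                      gamma = 200), x, r_max = 6)
  expect_equal(pa$emission_probs[-1, 2],
               ((2 - 1) + n1[-1]) / (2 * (2 - 1) + n[-1]), tolerance = 1e-12)

  # average at gamma = 200: exactly the order-0 posterior-mean predictive
  pv <- emission_stream(observer_spec("ngram_average", alpha = 2, beta = 1,
                                      gamma = 200), x, r_max = 6)
  expect_equal(pv$emission_probs[, 2], (2 + n1) / (4 + n), tolerance = 1e-9)

  # the collapsed MAP and posterior-mean streams approach each other as
  # counts accumulate (they differ by O(1/n) per trial)
  d <- abs(pa$emission_probs[, 2] - pv$emission_probs[, 2])
  expect_lt(max(d[100:120]), 0.02)
})
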