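# predstrat

Infer the prediction strategy of a sequence-learning observer from the
stimulus they saw and the guesses they made.

In a sequence-learning experiment, symbols from a binary alphabet are shown
one per trial and the observer predicts each upcoming symbol. `predstrat`
is for the experimenter on the other side of the table: given the stimulus
stream `s_1..s_t` and the aligned prediction stream `ŝ_1..ŝ_t`, it infers by
maximum likelihood *which algorithm* produced the predictions — a Bayesian
n-gram learner or a logistic-regression (GLM) pattern matcher — and bounds
the algorithm's parameters. It also simulates the forward problem (order-R
Markov stimuli, probability-matching observers, clone ensembles), so the
whole inference pipeline can be validated on data with known ground truth.

## The models

**Stimuli** are order-R Markov chains: `P(s_{t+1} | history) =
P(s_{t+1} | last R symbols)`.

**Observers** probability match: they guess symbol `s` with probability
equal to their current estimate `q(s)`. Three strategies are implemented:

* *n-gram argmax* — Bayesian model selection over Markov orders with the
  complexity prior `P(M_R) ∝ exp(−γ(|A|−1)|A|^R)` and Dirichlet(α) priors
  per context; predicts with the MAP-order, MAP-parameter predictive
  `(α + βn(cs) − 1) / (|A|(α−1) + βn(c))`, all counts discounted by the
  memory parameter β.
* *n-gram average* — the prior-weighted mixture over orders of per-order
  posterior-mean predictives `(α + βn(c_R s)) / (|A|α + βn(c_R))`.
* *GLM* — a ridge-penalized logistic regression of the next symbol on the
  last k symbols, refit every trial.

The likelihood of a prediction stream under a candidate is
`Σ_t log p_model(ŝ_t | s_1..s_{t−1})`; with infinitely many identical
observers it becomes a per-trial cross-entropy, maximized exactly at the
true strategy. Individual n-gram parameters are identifiable only up to a
multiplicative constant; the identifiable ratios are `φ = β/(α−1)` (argmax)
and `φ = β/α` (average), and `grid_search()` reports them as intervals over
all grid points tied at the maximum.

## Worked example

```r
library(predstrat)

model <- sample_markov_model(order = 2, seed = 11)
model
#> order-2 Markov model over {0, 1}
#>         0      1
#> 00 0.2657 0.7343
#> 01 0.7798 0.2202
#> 10 0.8684 0.1316
#> 11 0.6885 0.3115

stim  <- generate_stimulus(model, length = 500, seed = 12)
truth <- observer_spec("ngram_average", alpha = 1, beta = 0.5, gamma = 0.5)
trace <- simulate_observer(truth, stim, seed = 13)

cls <- classify_strategy(stim, trace$predictions)
cls$label;  round(cls$log_liks, 2)
#> [1] "ngram_average"
#>  ngram_argmax ngram_average           glm
#>       -383.77       -330.78       -340.49

cls$results$ngram_average
#> grid-search MLE for ngram_average: max log-likelihood -330.7800 at 1 point(s)
#>   phi in [1, 1], gamma in [0.5, 0.5]
```

The *class* of the strategy is recovered (`ngram_average`, i.e. Bayesian:
its maximized log-likelihood −330.78 beats the best GLM at −340.49 and the
best argmax candidate at −383.77). The *parameters* are not: the true
observer has `φ = β/α = 0.5`, but this single 500-trial prediction string is
best fit at `φ = 1`. That asymmetry — single observers reveal the strategy
class, parameter recovery needs clone ensembles — is the central
phenomenon the package quantifies. With infinite-clone evidence the
parameters do pin down exactly:

```r
p_obs <- emission_stream(truth, stim)$emission_probs   # analytic evidence
grid_search(stim, p_obs, "ngram_average",
            list(alpha = c(1, 2, 3), beta = c(0.5, 1), gamma = c(0.5, 2)))
#> grid-search MLE for ngram_average: max log-likelihood -331.6910 at 2 point(s)
#>   phi in [0.5, 0.5], gamma in [0.5, 0.5]
```

(the two tied points are the rescaling ray `(α, β) = (1, 0.5)` and
`(2, 1)` — the same observer).

Model-recovery experiments wrap this loop: `confusion_experiment()` tallies
inferred versus actual strategy class over a simulated cohort, and
`recovery_experiment()` measures lower/upper-bound φ errors from
infinite-clone evidence across stimulus orders and lengths.

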