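# bernstack

Exact Bayesian model comparison for exchangeable binary data: marginal
likelihoods, Bayes factors, Bayesian model averaging (BMA), exact
leave-one-out (LOO) predictive densities, stacking weights, and the
prequential decomposition of the marginal likelihood — all in closed form
for conjugate Bernoulli models.

## The problem

Given exchangeable binary outcomes `y = (y_1, …, y_n)` with `s` successes
and `f = n − s` failures, and a set of candidate models `M_1, …, M_M` for
the Bernoulli rate θ, the package compares three ways of combining the
models:

* **BMA**: posterior model probabilities
  `p(M_k | y) ∝ p(M_k) p(y | M_k)` weight each model's posterior and
  predictive. The predictive for one new observation is
  `p(y_new | y) = Σ_k p(M_k | y) p(y_new | y, M_k)`.
* **Exact LOO**: by exchangeability and conjugacy,
  `p(y_i = v | y_−i, M_k) = p(y | M_k) / p(y_−i | M_k)` depends only on the
  held-out value `v`, so the full LOO table is two numbers per model — no
  refitting and no approximation.
* **Stacking**: weights `w` on the simplex maximizing the average log of
  the weighted LOO predictive density,
  `(1/n) Σ_i log Σ_k w_k p(y_i | y_−i, M_k)`,
  found by multiplicative updates on the concave objective.

Three model families are supported: a point mass at `θ_0` (a "general law"
when `θ_0 = 1`), a `Beta(a, b)` prior truncated and renormalized to an
interval `[l, u]`, and a discrete grid of rates with prior weights. Because
a continuous prior can be partitioned into truncated-interval models whose
prior probabilities equal the prior interval masses, the same machinery
shows that BMA over such a partition is *identical* to ordinary posterior
inference under the unpartitioned prior — the boundary between "parameter
estimation" and "model comparison" is a modelling choice, not a
mathematical one. Stacking, by contrast, can put weight 0 on the model with
the highest posterior probability, and the marginal likelihood — but not
any LOO-based score — factors exactly into one-step-ahead predictions.

## A worked example

Twenty observations, ten of them successes; a uniform prior on θ
partitioned at .25 and .75 into three interval models with prior
probabilities .25/.5/.25:

```r
library(bernstack)
fit <- bern_compare(partition_models(1, 1, c(0.25, 0.75)),
                    binary_data(successes = 10, failures = 10))
summary(fit)
#> Bayesian model comparison: 3 model(s), binary_data(s = 10, f = 10)
#>                  label log_marginal posterior_prob stacking_weight
#>     theta in [0, 0.25]     -18.8329         0.0064             0.5
#>  theta in [0.25, 0.75]     -14.4911         0.9872             0.0
#>     theta in [0.75, 1]     -18.8329         0.0064             0.5
#> BMA predictive P(success):      0.5000
#> Stacking predictive P(success): 0.5000
#>
#> Exact LOO predictive densities:
#>         theta in [0, 0.25] theta in [0.25, 0.75] theta in [0.75, 1]
#> y_i = 0             0.7758                0.4786             0.2206
#> y_i = 1             0.2206                0.4786             0.7758
```

The middle model receives posterior probability .99 (BMA), yet stacking
assigns it weight 0, splitting all weight between the two mirrored extreme
models: their *combination* predicts each held-out observation with density
`.5 × .7758 + .5 × .2206 ≈ .4982`, better than the middle model's `.4786`
alone. Both BMA and stacking predict the next observation to be a success
with probability .5.

Other packaged examples: `run_scenario("tumor_grid")` (a discrete grid of
take probabilities `(1/2)^k` for tumor transplantability, where the grid
posterior is simultaneously a parameter posterior and a set of posterior
model probabilities), `run_scenario("general_law", n = 10)` (the point mass
at θ = 1 takes stacking weight 1 under all-success data, for every n), and
`run_scenario("single_failure")` (one counterexample gives the general law
marginal likelihood 0 and Bayes factor 0 against any alternative).

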