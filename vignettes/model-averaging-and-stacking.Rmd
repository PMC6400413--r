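---
title: "Exact model averaging, stacking and leave-one-out for Bernoulli models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact model averaging, stacking and leave-one-out for Bernoulli models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bernstack)
```

## The model families and their marginal likelihoods

All computations concern exchangeable binary outcomes
$y = (y_1, \dots, y_n)$ with $s$ successes and $f = n - s$ failures, and
candidate models for the Bernoulli rate $\theta$. Three conjugate families
are supported, each with a closed-form marginal likelihood under the
*ordered-sequence* convention $p(y \mid M) = \int \theta^s
(1-\theta)^f \, \pi_M(\theta)\, d\theta$ (no binomial coefficient):

* **Point mass** at $\theta_0$:
  $p(y \mid M) = \theta_0^s (1 - \theta_0)^f$, with $0 \log 0 := 0$.
  With $\theta_0 = 1$ this is a *general law* ("all swans are white"): a
  single failure gives it marginal likelihood exactly 0.
* **Truncated beta interval**: a $\mathrm{Beta}(a, b)$ prior renormalized
  to $[l, u]$. Then
  $p(y \mid M) = \frac{B(a+s,\, b+f)}{B(a, b)} \cdot
  \frac{F_{a+s,b+f}(u) - F_{a+s,b+f}(l)}{F_{a,b}(u) - F_{a,b}(l)}$,
  where $F_{a,b}$ is the regularized incomplete beta function, and the
  posterior is $\mathrm{Beta}(a+s, b+f)$ truncated to the same interval.
* **Discrete grid**: rates $\theta_k$ with prior weights $w_k$;
  $p(y \mid M) = \sum_k w_k \theta_k^s (1-\theta_k)^f$.

The sequence convention is stated once, globally: every quantity the
package reports — Bayes factors, posterior model probabilities, LOO
conditionals, posterior predictives, grid posteriors — is a ratio in which
the binomial coefficient would cancel, so the convention is immaterial (a
test verifies this by injecting the coefficient and re-deriving).

## Model averaging and the partition equivalence

With prior model probabilities $p(M_k)$, posterior model probabilities are
$p(M_k \mid y) \propto p(M_k)\, p(y \mid M_k)$, accumulated by
log-sum-exp; a falsified model is retained with probability exactly 0
rather than dropped, since "this model is ruled out" is itself the result.
The BMA predictive and posterior follow by mixing.

`partition_models(a, b, cutpoints)` splits $[0,1]$ into truncated-interval
models with prior probabilities equal to the base prior's interval masses.
For any such partition, BMA reproduces ordinary posterior inference under
the unpartitioned prior *exactly*: the mixture of truncated posteriors
weighted by posterior model probabilities equals the untruncated
$\mathrm{Beta}(a+s, b+f)$ posterior, because the posterior model
probability of each interval is precisely the untruncated posterior's mass
in it, and mass times renormalized density restores the unrestricted
density. The property suite checks this to $10^{-10}$ relative error on a
1001-point grid over randomized bases, cutpoint sets of size up to 4 and
counts up to 30 — sizes at which the identity already exercises every
branch of the incomplete-beta arithmetic while keeping the default test
run a few seconds.

## Exact leave-one-out and stacking

Exchangeability makes exact LOO a two-number-per-model affair:
$p(y_i = v \mid y_{-i}, M) = p(y \mid M) / p(y_{-i} \mid M)$ depends only
on the held-out value $v \in \{0, 1\}$. A value that does not occur in the
data has no held-out conditional (the entry is `NA`); a model under which
some $y_{-i}$ has probability 0 has a $0/0$ conditional and is flagged
undefined.

Stacking maximizes
$\frac{1}{n} \sum_i \log \sum_k w_k\, p(y_i \mid y_{-i}, M_k)$
over the simplex. The objective is concave, and its optimum may sit on the
boundary (weights exactly 0 or 1), so the optimizer uses multiplicative
updates $w_k \leftarrow w_k \,\partial_k / \sum_j w_j \partial_j$ (with
$\partial_k$ the gradient), which stay on the simplex and approach boundary
optima geometrically. Convergence requires objective improvement below
$10^{-12}$ *and* weight change below $10^{-8}$, capped at $10^5$
iterations; afterwards weights below $10^{-6}$ are snapped to 0 and the
vector renormalized, accepted only if the objective loses less than
$10^{-10}$. Tests cross-check the optimizer against a dense simplex grid
search (step .001).

Design choices in edge cases:

* **Undefined conditionals.** A model with an undefined LOO entry (e.g. a
  general law when the data contain a failure elsewhere) is excluded from
  the simplex with weight fixed at 0 and a warning — any positive weight
  on a $0/0$ conditional is dominated.
* **Flat optima.** Duplicated or linearly redundant models leave the
  objective constant along a face of the simplex; the solution is then not
  identified (only the combined predictive is). The solver probes every
  edge of the simplex with a $10^{-3}$ weight transfer and sets
  `flat_optimum` when some transfer moves the objective by less than
  $10^{-10}$. Vertex-directed perturbations would miss this: mixing
  toward a vertex perturbs *all* coordinates and picks up curvature from
  the non-degenerate directions.
* **Stacked posterior mixtures.** `stacking_posterior_density()` averages
  parameter posteriors with stacking weights. This is illustrative only —
  stacking weights are defined for combining predictive distributions, and
  averaging posteriors with them has no decision-theoretic warrant; the
  function exists to show what such a mixture looks like (e.g. zero
  density at $\theta = .5$ in the three-interval example even though the
  data are symmetric around it).

## The prequential decomposition

The marginal likelihood factors exactly into one-step-ahead predictions,
$p(y \mid M) = \prod_i p(y_i \mid y_{1:i-1}, M)$, so Bayesian updating
gives the same answer whether data arrive one at a time or all at once;
`one_step_ahead()` records both sides of the identity and
`check_order_invariance()` verifies the product is permutation-invariant
(20 permutations by default under a fixed seed — the identity is exact, so
more permutations add information only about the RNG). No ordering of the
LOO factors reproduces this telescoping product: LOO conditions every
prediction on $n-1$ observations, which is precisely why it cannot serve
as a marginal likelihood substitute in sequential learning.

A zero factor (a falsified model mid-sequence) truncates the trace: later
conditionals are $0/0$ and reported `NA`, and the accumulated log marginal
is $-\infty$, matching the directly computed one.

## Numerical choices

* All beta-function work is in log space (`lbeta`, `pbeta`).
* Interval masses are differenced in the tail the interval lies in: for an
  interval in the lower tail, $F(u) - F(l)$ is a difference of small,
  relatively-accurate numbers, whereas the complement branch subtracts two
  numbers near 1 and cancels catastrophically (and vice versa). Intervals
  straddling the median are safe either way. This keeps deep-tail masses
  ($\sim 10^{-16}$ and below) to full relative precision, which the
  LOO-versus-refit equivalence tests exercise directly.
* Truncation intervals must carry at least $10^{-12}$ of the base prior's
  mass; below that, model construction fails loudly rather than producing
  unstable marginal-likelihood ratios.
* Open versus closed interval endpoints are not distinguished: endpoints
  have measure zero under every continuous prior here.
* Zero marginal likelihoods are represented as $-\infty$ on the log scale,
  never `NaN`; $0 \cdot \log 0 := 0$ for point masses.
* Density output grids default to 1001 equally spaced points in $[0, 1]$
  including endpoints.

## The synthetic-data generator and the packaged scenarios

`generate_bernoulli(n, theta, seed)` draws i.i.d. Bernoulli sequences with
a pinned seed and restores the caller's RNG state — it emulates exactly
the exchangeable, fixed-rate world the models assume. Real binary outcome
series with drift, serial dependence or heterogeneous units violate
exchangeability, and nothing here detects that; passing tests certify the
arithmetic of the methods, not the adequacy of the exchangeability
assumption for any particular data set.

The `scenario()` registry pins the four worked examples: the
three-interval partition with 10 successes in 20; the tumor
transplantability grid ($\theta_k = 2^{-k}$, $k = 1..10$, uniform prior, 1
take in 6 attempts); the general law versus a uniform alternative with $n$
all-success observations (default $n = 2$ — two white swans — since the
stacking result is invariant in $n$, with $n$ configurable to make that
invariance checkable); and the same pair with a single failure (default
$n = 20$). Successes encode law-consistent observations ("takes", white
swans). Scenario data are stored with all successes preceding all
failures, a canonical order that makes prequential traces well defined;
every scenario round-trips through the YAML configuration format.

## Limitations

Only Bernoulli outcome data and the three conjugate families are
supported: no non-conjugate likelihoods, no MCMC, no approximate LOO, and
no variance-corrected or pseudo-weighting schemes for combining models.
Stacking weights from data this small are themselves highly variable
objects; the package computes them exactly, which is not the same as
recommending decisions be based on them.
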