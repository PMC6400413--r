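Package: bernstack
Title: Exact Bayesian Model Averaging, Stacking and Leave-One-Out for Bernoulli Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Exact, closed-form Bayesian model comparison for exchangeable
    binary data under point-mass, truncated-beta-interval and discrete-grid
    priors on a Bernoulli rate. Provides log marginal likelihoods, Bayes
    factors, posterior model probabilities, Bayesian model averaging of
    posteriors and predictives, exact leave-one-out predictive densities,
    stacking weights obtained by maximizing the average log of the weighted
    leave-one-out predictive density over the simplex, the prequential
    (one-step-ahead) decomposition of the marginal likelihood, and the
    equivalence between model averaging over a partition of the parameter
    space and ordinary posterior inference under the unpartitioned prior.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
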