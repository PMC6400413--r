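test_that("LOO predictive table reproduces the three-interval values", {
  tab <- loo_table(fig2_models(), fig2_data())
  expect_equal(round(tab$q0, 4), c(0.7758, 0.4786, 0.2206))
  expect_equal(round(tab$q1, 4), c(0.2206, 0.4786, 0.7758))
  # s = f and mirrored intervals make the held-out-1 row the reverse of the
  # held-out-0 row
  expect_equal(tab$q1, rev(tab$q0), tolerance = 1e-12)
  expect_true(all(tab$defined))
})

test_that("marginal-ratio LOO equals an explicit refit of the reduced posterior", {
  set.seed(23)
  for (i in 1:12) {
    a <- runif(1, 0.5, 4); b <- runif(1, 0.5, 4)
    bounds <- sort(runif(2))
    n <- sample(2:25, 1); s <- sample(1:(n - 1), 1)
    m <- interval_model(a, b, bounds[1], bounds[2])
    d <- binary_data(successes = s, failures = n - s)
    tab <- loo_table(model_set(m), d)
    # refit oracle: truncated posterior on y_-i, predictive from its mean
    mean_minus_fail <- trunc_beta_mean(a + s, b + (n - s - 1),
                                       bounds[1], bounds[2])
    mean_minus_succ <- trunc_beta_mean(a + s - 1, b + (n - s),
                                       bounds[1], bounds[2])
    expect_equal(tab$q0, 1 - mean_minus_fail, tolerance = 1e-12)
    expect_equal(tab$q1, mean_minus_succ, tolerance = 1e-12)
    # exchangeability: removing any index with the same value gives the same
    # conditional as removing by count
    y <- sample(c(rep(1L, s), rep(0L, n - s)))
    lm_full <- log_marginal(m, binary_data(y))
    for (idx in c(match(0L, y), match(1L, y))) {
      q <- exp(lm_full - log_marginal(m, binary_data(y[-idx])))
      expect_equal(q, if (y[idx] == 0) tab$q0 else tab$q1, tolerance = 1e-12)
    }
  }
})

test_that("LOO table flags undefined conditionals and absent values", {
  # general law with a failure elsewhere: leaving out a success keeps the
  # failure, so p(y_-i | M) = 0 and the conditional is 0/0
  ms <- model_set(point_model(1), interval_model())
  tab <- loo_table(ms, binary_data(successes = 19, failures = 1))
  expect_false(tab$defined[1])
  expect_true(tab$defined[2])
  # all-success data: held-out-0 column is not applicable
  tab2 <- loo_table(ms, binary_data(successes = 5, failures = 0))
  expect_true(all(is.na(tab2$q0)))
  expect_equal(tab2$q1[1], 1)
  expect_equal(tab2$q1[2], 5 / 6, tolerance = 1e-12)  # Laplace on n-1 = 4
  expect_error(loo_table(ms, binary_data(successes = 1, failures = 0)),
               "at least 2")
})

test_that("weighted LOO densities reproduce the printed combinations", {
  tab <- loo_table(fig2_models(), fig2_data())
  expect_equal(round(combined_loo_density(c(0.5, 0, 0.5), tab, 0), 4), 0.4982)
  expect_equal(round(combined_loo_density(c(0.5, 0, 0.5), tab, 1), 4), 0.4982)
  expect_equal(round(combined_loo_density(c(0, 1, 0), tab, 0), 4), 0.4786)
  expect_equal(round(combined_loo_density(rep(1, 3) / 3, tab, 0), 4), 0.4917)
})

test_that("stacking objective is the count-weighted mean log combined density", {
  tab <- loo_table(fig2_models(), fig2_data())
  w <- c(0.5, 0, 0.5)
  expect_equal(stacking_objective(w, tab),
               log(combined_loo_density(w, tab, 0)), tolerance = 1e-12)
  expect_gt(stacking_objective(w, tab), stacking_objective(c(0, 1, 0), tab))
  # a model predicting 1/2 for both values scores log(1/2) on any data
  fair <- model_set(point_model(0.5))
  tabf <- loo_table(fair, binary_data(successes = 3, failures = 4))
  expect_equal(stacking_objective(1, tabf), log(0.5), tolerance = 1e-12)
  # weight on an undefined model errors
  ms <- model_set(point_model(1), interval_model())
  tabu <- loo_table(ms, binary_data(successes = 19, failures = 1))
  expect_error(combined_loo_density(c(0.5, 0.5), tabu, 0), "undefined")
})

test_that("stacking optimum splits weight over the two mirrored extreme models", {
  tab <- loo_table(fig2_models(), fig2_data())
  sol <- expect_warning(stacking_weights(tab), NA)
  expect_true(sol$converged)
  expect_false(sol$flat_optimum)
  expect_equal(unname(sol$weights), c(0.5, 0, 0.5), tolerance = 1e-3)
  expect_identical(unname(sol$weights[2]), 0)
  # dense grid-search cross-check
  gs <- grid_search_stacking(rbind(tab$q0, tab$q1), c(10, 10))
  expect_equal(unname(sol$weights), gs$weights, tolerance = 1e-3)
  expect_lt(abs(sol$objective_value - gs$objective), 1e-8)
  expect_gte(sol$objective_value, gs$objective - 1e-12)
})

test_that("optimizer matches grid search on random two-model problems", {
  set.seed(31)
  for (i in 1:6) {
    a <- runif(1, 0.5, 3); b <- runif(1, 0.5, 3)
    cut <- runif(1, 0.2, 0.8)
    ms <- partition_models(a, b, cut)
    n <- sample(4:20, 1); s <- sample(1:(n - 1), 1)
    d <- binary_data(successes = s, failures = n - s)
    tab <- loo_table(ms, d)
    sol <- stacking_weights(tab)
    gs <- grid_search_stacking(rbind(tab$q0, tab$q1), c(n - s, s))
    expect_equal(unname(sol$weights), gs$weights, tolerance = 2e-3)
    expect_gte(sol$objective_value, gs$objective - 1e-12)
  }
})

test_that("all-success data give the general law full stacking weight, any n", {
  for (n in c(2, 5, 10, 100)) {
    ms <- model_set(point_model(1), interval_model())
    tab <- loo_table(ms, binary_data(successes = n, failures = 0))
    sol <- stacking_weights(tab)
    expect_equal(unname(sol$weights[1]), 1, tolerance = 1e-3)
    expect_equal(stacking_predictive(sol, ms,
                                     binary_data(successes = n, failures = 0)),
                 1, tolerance = 1e-3)
  }
})

test_that("falsified models are excluded from the stacking simplex", {
  ms <- model_set(point_model(1), interval_model())
  tab <- loo_table(ms, binary_data(successes = 19, failures = 1))
  expect_warning(sol <- stacking_weights(tab), "excluding")
  expect_identical(unname(sol$weights[1]), 0)
  expect_equal(unname(sol$weights[2]), 1)
  expect_equal(sol$excluded, tab$model_label[1])
})

test_that("duplicated models leave the optimum flat and are flagged", {
  m <- fig2_models()
  ms <- model_set(m$models[[1]], m$models[[2]], m$models[[3]],
                  interval_model(lower = 0, upper = 0.25, label = "dup of 1"))
  tab <- loo_table(ms, fig2_data())
  sol <- stacking_weights(tab)
  expect_true(sol$flat_optimum)
  # the combined predictive is still identified
  expect_equal(combined_loo_density(unname(sol$weights), tab, 0), 0.4982,
               tolerance = 1e-4)
})

test_that("replicating the data composition leaves stacking weights unchanged", {
  ms <- fig2_models()
  sol1 <- stacking_weights(loo_table(ms, binary_data(successes = 10,
                                                     failures = 10)))
  sol3 <- stacking_weights(loo_table(ms, binary_data(successes = 30,
                                                     failures = 30)))
  # weights respond only through the per-value LOO densities, which shift a
  # little with n; the optimum stays at the symmetric split exactly
  expect_equal(unname(sol1$weights), c(0.5, 0, 0.5), tolerance = 1e-3)
  expect_equal(unname(sol3$weights), c(0.5, 0, 0.5), tolerance = 1e-3)
})

test_that("singleton model sets and degenerate inputs are handled", {
  tab <- loo_table(model_set(interval_model()), binary_data(c(1, 0, 1)))
  sol <- stacking_weights(tab)
  expect_equal(unname(sol$weights), 1)
  ms <- model_set(point_model(1, label = "law"), point_model(1, label = "law2"))
  tabu <- loo_table(ms, binary_data(successes = 3, failures = 1))
  expect_error(suppressWarnings(stacking_weights(tabu)), "infeasible")
})

test_that("stacking mixture density behaves like a mixture", {
  ms <- fig2_models()
  d <- fig2_data()
  sol <- stacking_weights(loo_table(ms, d))
  # theta = .5 lies outside the supports of both extreme models
  expect_identical(stacking_posterior_density(sol, ms, d, 0.5), 0)
  # integrate piecewise: the mixture density jumps at the cutpoints
  dens_int <- sum(vapply(list(c(0, 0.25), c(0.25, 0.75), c(0.75, 1)),
                         function(iv) stats::integrate(function(t)
                           stacking_posterior_density(sol, ms, d, t),
                           iv[1], iv[2], rel.tol = 1e-10)$value, numeric(1)))
  expect_equal(dens_int, 1, tolerance = 1e-8)
  # degenerate weights reproduce one model's truncated posterior
  sol010 <- sol; sol010$weights <- c(0, 1, 0)
  grid <- seq(0, 1, by = 0.01)
  expect_equal(stacking_posterior_density(sol010, ms, d, grid),
               posterior_density(ms$models[[2]], d, grid), tolerance = 1e-12)
})
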