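# Independent oracles used across the test files. These deliberately avoid
# the package's lbeta-based closed forms: marginal likelihoods by adaptive
# quadrature, grid posteriors by direct enumeration, stacking optima by
# dense simplex grid search.

# log marginal likelihood of a truncated-beta interval model by quadrature
quad_log_marginal <- function(base_a, base_b, lower, upper, s, f) {
  prior_mass <- stats::integrate(function(t) stats::dbeta(t, base_a, base_b),
                                 lower, upper, rel.tol = 1e-13)$value
  val <- stats::integrate(function(t) {
    t^s * (1 - t)^f * stats::dbeta(t, base_a, base_b) / prior_mass
  }, lower, upper, rel.tol = 1e-13)$value
  log(val)
}

# mean of Beta(a, b) truncated to [l, u], via the incomplete-beta identity
# theta * dbeta(theta, a, b) = (a / (a + b)) * dbeta(theta, a + 1, b).
# Masses are differenced in the tail the interval lies in, so deep-tail
# truncations keep full relative precision.
oracle_mass <- function(a, b, l, u) {
  p_u <- stats::pbeta(u, a, b)
  if (p_u <= 0.5) return(p_u - stats::pbeta(l, a, b))
  q_l <- stats::pbeta(l, a, b, lower.tail = FALSE)
  if (q_l <= 0.5) return(q_l - stats::pbeta(u, a, b, lower.tail = FALSE))
  p_u - stats::pbeta(l, a, b)
}

trunc_beta_mean <- function(a, b, l, u) {
  a / (a + b) * oracle_mass(a + 1, b, l, u) / oracle_mass(a, b, l, u)
}

# posterior over a discrete grid by brute-force enumeration
enum_grid_posterior <- function(values, weights, s, f) {
  terms <- weights * values^s * (1 - values)^f
  terms / sum(terms)
}

# maximize the stacking objective over the simplex by dense grid search;
# q is a matrix (values-in-data x models), cnt the per-value counts
grid_search_stacking <- function(q, cnt, step = 0.001) {
  m <- ncol(q)
  n <- sum(cnt)
  obj <- function(w) {
    dens <- as.numeric(q %*% w)
    if (any(dens <= 0)) return(-Inf)
    sum(cnt * log(dens)) / n
  }
  if (m == 1) return(list(weights = 1, objective = obj(1)))
  grid1 <- seq(0, 1, by = step)
  best <- NULL; best_obj <- -Inf
  if (m == 2) {
    for (w1 in grid1) {
      o <- obj(c(w1, 1 - w1))
      if (o > best_obj) { best_obj <- o; best <- c(w1, 1 - w1) }
    }
  } else if (m == 3) {
    for (w1 in grid1) {
      w2max <- 1 - w1
      for (w2 in seq(0, w2max, by = step)) {
        o <- obj(c(w1, w2, 1 - w1 - w2))
        if (o > best_obj) { best_obj <- o; best <- c(w1, w2, 1 - w1 - w2) }
      }
    }
  } else stop("grid search implemented for up to 3 models")
  list(weights = best, objective = best_obj)
}

# the worked three-interval scenario used in many tests
fig2_models <- function() partition_models(1, 1, c(0.25, 0.75))
fig2_data <- function() binary_data(c(rep(1L, 10), rep(0L, 10)))
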