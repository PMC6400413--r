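#' Bernoulli model families
#'
#' Three conjugate model families for a Bernoulli rate theta:
#' a point mass (a "general law" when `theta0 = 1`), a beta prior truncated
#' and renormalized to an interval, and a discrete grid of rates with prior
#' weights. All downstream quantities (marginal likelihoods, Bayes factors,
#' leave-one-out predictive densities, stacking weights) are available in
#' closed form for these families.
#'
#' Marginal likelihoods use the ordered-sequence convention throughout: the
#' probability of one particular 0/1 sequence, without the binomial
#' coefficient. Every reported quantity is a ratio of marginal likelihoods
#' in which that data-dependent constant cancels, so results are identical
#' under the counts (binomial) convention.
#'
#' Interval endpoints are treated as zero-measure under the continuous base
#' prior, so open versus closed endpoints are not distinguished; validation
#' only requires `lower < upper`. Construction fails if the base beta prior
#' puts mass below 1e-12 on the interval, since marginal-likelihood ratios
#' become numerically unstable there.
#'
#' @param theta0 Bernoulli rate in [0, 1] asserted by the point-mass model.
#' @param base_a,base_b positive shape parameters of the untruncated beta
#'   base prior.
#' @param lower,upper truncation interval bounds, `0 <= lower < upper <= 1`.
#' @param values ordered distinct Bernoulli rates of a discrete grid.
#' @param weights prior probabilities on `values`, summing to 1.
#' @param label free-text model label used in reports.
#' @return A model object of class `point_model`, `interval_model` or
#'   `grid_model`, all inheriting from `bern_model`.
#' @examples
#' point_model(1, label = "general law")
#' interval_model(lower = 0.25, upper = 0.75)
#' grid_model(values = 2^-(1:10), weights = rep(0.1, 10))
#' @name bern_models
NULL

#' @rdname bern_models
#' @export
point_model <- function(theta0, label = sprintf("theta = %g", theta0)) {
  stopifnot(is.numeric(theta0), length(theta0) == 1L, is.finite(theta0))
  if (theta0 < 0 || theta0 > 1)
    stop("`theta0` must lie in [0, 1]", call. = FALSE)
  structure(list(theta0 = theta0, label = label),
            class = c("point_model", "bern_model"))
}

#' @rdname bern_models
#' @export
interval_model <- function(base_a = 1, base_b = 1, lower = 0, upper = 1,
                           label = sprintf("theta in [%g, %g]", lower, upper)) {
  stopifnot(is.numeric(base_a), is.numeric(base_b), base_a > 0, base_b > 0)
  if (!(lower >= 0 && upper <= 1 && lower < upper))
    stop("need 0 <= lower < upper <= 1", call. = FALSE)
  pm <- beta_interval_mass(base_a, base_b, lower, upper)
  if (pm <= 1e-12)
    stop(sprintf(
      "base Beta(%g, %g) prior mass on [%g, %g] is %.3e (below 1e-12); ",
      base_a, base_b, lower, upper, pm),
      "renormalization would be numerically unstable", call. = FALSE)
  structure(list(base_a = base_a, base_b = base_b,
                 lower = lower, upper = upper, label = label),
            class = c("interval_model", "bern_model"))
}

#' @rdname bern_models
#' @export
grid_model <- function(values, weights = rep(1 / length(values), length(values)),
                       label = "grid model") {
  stopifnot(is.numeric(values), is.numeric(weights),
            length(values) == length(weights), length(values) >= 1L)
  if (any(values < 0 | values > 1)) stop("grid values must lie in [0, 1]",
                                         call. = FALSE)
  if (anyDuplicated(values)) stop("grid values must be distinct", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("grid weights must be nonnegative and sum to 1", call. = FALSE)
  structure(list(grid_values = as.numeric(values),
                 prior_weights = as.numeric(weights), label = label),
            class = c("grid_model", "bern_model"))
}

#' @export
print.bern_model <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.point_model <- function(x, ...) {
  sprintf("Point-mass model '%s': theta = %g", x$label, x$theta0)
}

#' @export
format.interval_model <- function(x, ...) {
  sprintf("Interval model '%s': Beta(%g, %g) truncated to [%g, %g]",
          x$label, x$base_a, x$base_b, x$lower, x$upper)
}

#' @export
format.grid_model <- function(x, ...) {
  sprintf("Grid model '%s': %d support points", x$label,
          length(x$grid_values))
}

# mass of Beta(a, b) on [l, u]. The branch matters: differencing the tail
# the interval actually lies in keeps tiny masses to full relative
# precision, while the opposite branch cancels catastrophically (two values
# near 1 differing in the 16th digit). Intervals straddling the median are
# safe in either branch.
beta_interval_mass <- function(a, b, l, u) {
  p_u <- stats::pbeta(u, a, b)
  if (p_u <= 0.5)
    return(max(p_u - stats::pbeta(l, a, b), 0))
  q_l <- stats::pbeta(l, a, b, lower.tail = FALSE)
  if (q_l <= 0.5)
    return(max(q_l - stats::pbeta(u, a, b, lower.tail = FALSE), 0))
  max(p_u - stats::pbeta(l, a, b), 0)
}

log_beta_interval_mass <- function(a, b, l, u) {
  m <- beta_interval_mass(a, b, l, u)
  if (m <= 0) -Inf else log(m)
}

# x * log(p) with the 0 * log 0 := 0 convention
xlogp <- function(x, p) {
  if (x == 0) return(0)
  if (p <= 0) return(-Inf)
  x * log(p)
}

log_sum_exp <- function(lx) {
  if (all(lx == -Inf)) return(-Inf)
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

#' Log marginal likelihood of binary data under a Bernoulli model
#'
#' Computes `log p(y | M)` under the ordered-sequence convention (no binomial
#' coefficient). For a point mass at `theta0` this is
#' `s * log(theta0) + f * log(1 - theta0)` with `0 * log 0 := 0`; for a
#' truncated-beta interval model it is the beta-function ratio times the
#' ratio of posterior to prior interval masses; for a grid model it is the
#' log of the prior-weighted sum of likelihood terms.
#'
#' Data with probability zero under the model (e.g. a failure under a point
#' mass at 1) yield `-Inf`, never an error or `NaN`.
#'
#' @param model a `bern_model`.
#' @param data a [binary_data] object (or a 0/1 vector).
#' @return a single number, finite or `-Inf`.
#' @examples
#' log_marginal(point_model(1), binary_data(successes = 5, failures = 0))
#' log_marginal(interval_model(), binary_data(successes = 1, failures = 1))
#' @export
log_marginal <- function(model, data) UseMethod("log_marginal")

#' @export
log_marginal.point_model <- function(model, data) {
  data <- as_binary_data(data)
  xlogp(data$s, model$theta0) + xlogp(data$f, 1 - model$theta0)
}

#' @export
log_marginal.interval_model <- function(model, data) {
  data <- as_binary_data(data)
  a <- model$base_a; b <- model$base_b
  post_mass <- log_beta_interval_mass(a + data$s, b + data$f,
                                      model$lower, model$upper)
  if (post_mass == -Inf) return(-Inf)
  lbeta(a + data$s, b + data$f) - lbeta(a, b) + post_mass -
    log_beta_interval_mass(a, b, model$lower, model$upper)
}

#' @export
log_marginal.grid_model <- function(model, data) {
  data <- as_binary_data(data)
  lt <- mapply(function(w, th) {
    if (w == 0) return(-Inf)
    log(w) + xlogp(data$s, th) + xlogp(data$f, 1 - th)
  }, model$prior_weights, model$grid_values)
  log_sum_exp(lt)
}

#' Truncated posterior density of the Bernoulli rate
#'
#' Density of the posterior `Beta(base_a + s, base_b + f)` truncated and
#' renormalized to the model's interval, evaluated at `theta`. Zero outside
#' the interval; integrates to 1 over [0, 1].
#'
#' @param model an [interval_model].
#' @param data a [binary_data] object.
#' @param theta evaluation points in [0, 1] (vectorized).
#' @return nonnegative density values, same length as `theta`.
#' @export
posterior_density <- function(model, data, theta) UseMethod("posterior_density")

#' @export
posterior_density.interval_model <- function(model, data, theta) {
  data <- as_binary_data(data)
  stopifnot(all(theta >= 0 & theta <= 1))
  a <- model$base_a + data$s; b <- model$base_b + data$f
  mass <- beta_interval_mass(a, b, model$lower, model$upper)
  if (mass <= 0)
    stop("posterior mass on the interval underflows to 0", call. = FALSE)
  d <- stats::dbeta(theta, a, b) / mass
  d[theta < model$lower | theta > model$upper] <- 0
  d
}

#' @export
posterior_density.bern_model <- function(model, data, theta) {
  stop(sprintf("model '%s' has no density with respect to Lebesgue measure",
               model$label), call. = FALSE)
}

#' Posterior predictive probability of a success
#'
#' The probability that one new observation is a success given the data,
#' `p(y_new = 1 | y, M) = p(y + one success | M) / p(y | M)`. For an interval
#' model this equals the mean of the truncated posterior; for a point-mass
#' model it is `theta0`.
#'
#' @param model a `bern_model`.
#' @param data a [binary_data] object; its marginal likelihood under `model`
#'   must be positive, otherwise the conditional probability is undefined and
#'   an error is thrown.
#' @return a probability in [0, 1].
#' @examples
#' predictive_success(interval_model(), binary_data(successes = 10, failures = 10))
#' @export
predictive_success <- function(model, data) {
  data <- as_binary_data(data)
  lm0 <- log_marginal(model, data)
  if (lm0 == -Inf)
    stop(sprintf(
      "data have probability 0 under model '%s'; the predictive is undefined",
      model$label), call. = FALSE)
  p <- exp(log_marginal(model, augment_data(data, add_s = 1L)) - lm0)
  min(max(p, 0), 1)
}

#' Posterior over the support points of a grid model
#'
#' `p(theta_k | y)` proportional to `w_k * theta_k^s * (1 - theta_k)^f`,
#' normalized to sum to 1. When the grid indexes scientific hypotheses these
#' are posterior model probabilities; when it discretizes a parameter they
#' are an ordinary parameter posterior — the two readings are numerically
#' identical.
#'
#' @param model a [grid_model].
#' @param data a [binary_data] object.
#' @return a probability vector over `model$grid_values`.
#' @examples
#' tumor <- grid_model(values = 2^-(1:10), weights = rep(0.1, 10))
#' grid_posterior(tumor, binary_data(successes = 1, failures = 5))
#' @export
grid_posterior <- function(model, data) {
  stopifnot(inherits(model, "grid_model"))
  data <- as_binary_data(data)
  lt <- mapply(function(w, th) {
    if (w == 0) return(-Inf)
    log(w) + xlogp(data$s, th) + xlogp(data$f, 1 - th)
  }, model$prior_weights, model$grid_values)
  tot <- log_sum_exp(lt)
  if (tot == -Inf)
    stop("data have probability 0 at every grid value", call. = FALSE)
  exp(lt - tot) / sum(exp(lt - tot))
}
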