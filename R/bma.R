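#' A set of candidate Bernoulli models
#'
#' Bundles models with optional prior model probabilities. Priors are
#' required for posterior model probabilities and Bayesian model averaging;
#' leave-one-out stacking needs none.
#'
#' @param ... model objects (see [bern_models]), or a single list of them.
#' @param prior_probs optional prior model probabilities, nonnegative and
#'   summing to 1 (tolerance 1e-12).
#' @return an object of class `model_set`.
#' @examples
#' model_set(point_model(1), interval_model(), prior_probs = c(0.5, 0.5))
#' @export
model_set <- function(..., prior_probs = NULL) {
  models <- list(...)
  if (length(models) == 1L && !inherits(models[[1L]], "bern_model") &&
      is.list(models[[1L]]))
    models <- models[[1L]]
  if (length(models) == 0L) stop("need at least one model", call. = FALSE)
  ok <- vapply(models, inherits, logical(1), what = "bern_model")
  if (!all(ok)) stop("all elements must be Bernoulli models", call. = FALSE)
  labels <- vapply(models, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("model labels must be unique", call. = FALSE)
  if (!is.null(prior_probs)) {
    stopifnot(length(prior_probs) == length(models))
    if (any(prior_probs < 0) || abs(sum(prior_probs) - 1) > 1e-12)
      stop("`prior_probs` must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(models = models, prior_probs = prior_probs, labels = labels),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("Model set with %d models:\n", length(x$models)))
  for (i in seq_along(x$models)) {
    pp <- if (is.null(x$prior_probs)) "" else
      sprintf("  [prior %.4g]", x$prior_probs[i])
    cat(sprintf("  %d. %s%s\n", i, format(x$models[[i]]), pp))
  }
  invisible(x)
}

#' @export
length.model_set <- function(x) length(x$models)

#' Posterior model probabilities
#'
#' `p(M_k | y)` proportional to `p(M_k) * p(y | M_k)`, computed through
#' log-sum-exp so that raw marginal likelihoods are never exponentiated
#' first. A model whose marginal likelihood is zero (e.g. a falsified
#' general law) is retained with posterior probability exactly 0.
#'
#' @param model_set a [model_set] with `prior_probs` set.
#' @param data a [binary_data] object.
#' @return a probability vector named by model labels.
#' @export
posterior_model_probs <- function(model_set, data) {
  stopifnot(inherits(model_set, "model_set"))
  if (is.null(model_set$prior_probs))
    stop("`model_set` has no prior model probabilities", call. = FALSE)
  data <- as_binary_data(data)
  lm <- vapply(model_set$models, log_marginal, numeric(1), data = data)
  lp <- ifelse(model_set$prior_probs > 0,
               log(model_set$prior_probs) + lm, -Inf)
  tot <- log_sum_exp(lp)
  if (tot == -Inf)
    stop("all models assign probability 0 to the data", call. = FALSE)
  p <- exp(lp - tot)
  p <- p / sum(p)
  names(p) <- model_set$labels
  p
}

#' Bayes factor between two models
#'
#' The ratio of marginal likelihoods `p(y | M_a) / p(y | M_b)`, computed on
#' the log scale. Returns `Inf` or `0` when exactly one marginal likelihood
#' is zero; errors when both are (the ratio is then undefined).
#'
#' @param model_a,model_b `bern_model` objects.
#' @param data a [binary_data] object.
#' @param log if `TRUE` return the log Bayes factor.
#' @return a nonnegative number, possibly `0` or `Inf`.
#' @examples
#' # a single failure falsifies the general law against a uniform alternative
#' bayes_factor(point_model(1), interval_model(),
#'              binary_data(successes = 19, failures = 1))
#' @export
bayes_factor <- function(model_a, model_b, data, log = FALSE) {
  data <- as_binary_data(data)
  la <- log_marginal(model_a, data)
  lb <- log_marginal(model_b, data)
  if (la == -Inf && lb == -Inf)
    stop("both marginal likelihoods are 0; the Bayes factor is undefined",
         call. = FALSE)
  lbf <- la - lb
  if (log) lbf else exp(lbf)
}

#' Model-averaged predictive probability of a success
#'
#' The Bayesian-model-averaging predictive for one new observation:
#' posterior-model-probability-weighted average of each model's posterior
#' predictive success probability. Models with posterior probability 0
#' contribute nothing even when their own predictive is undefined.
#'
#' @inheritParams posterior_model_probs
#' @return a probability in [0, 1].
#' @export
bma_predictive <- function(model_set, data) {
  data <- as_binary_data(data)
  post <- unname(posterior_model_probs(model_set, data))
  pred <- vapply(seq_along(post), function(k) {
    if (post[k] == 0) return(0)
    predictive_success(model_set$models[[k]], data)
  }, numeric(1))
  sum(post * pred)
}

#' Model-averaged posterior density of the Bernoulli rate
#'
#' The mixture of per-model truncated posterior densities with posterior
#' model probabilities as weights, evaluated pointwise on `theta_grid`.
#' Defined for sets of interval models (the other families carry no density
#' with respect to Lebesgue measure).
#'
#' @inheritParams posterior_model_probs
#' @param theta_grid evaluation points in [0, 1]; default 1001 equally
#'   spaced points including the endpoints.
#' @return density values on `theta_grid`.
#' @export
bma_posterior_density <- function(model_set, data,
                                  theta_grid = seq(0, 1, length.out = 1001)) {
  data <- as_binary_data(data)
  stopifnot(all(theta_grid >= 0 & theta_grid <= 1))
  post <- unname(posterior_model_probs(model_set, data))
  dens <- numeric(length(theta_grid))
  for (k in seq_along(post)) {
    if (post[k] == 0) next
    dens <- dens + post[k] *
      posterior_density(model_set$models[[k]], data, theta_grid)
  }
  dens
}

#' Partition a beta prior into interval models
#'
#' Splits `[0, 1]` at the given cutpoints into truncated-beta interval
#' models sharing the base prior, with prior model probabilities equal to
#' the base prior's mass in each interval. Model averaging over such a
#' partition reproduces, exactly, ordinary posterior inference under the
#' unpartitioned `Beta(base_a, base_b)` prior — partitioning a parameter
#' space relabels an estimation problem as a model-comparison problem
#' without changing any posterior quantity.
#'
#' @param base_a,base_b positive shape parameters of the base beta prior.
#' @param cutpoints strictly increasing values inside (0, 1); may be empty.
#' @return a [model_set] of `length(cutpoints) + 1` interval models with
#'   partition-induced `prior_probs`.
#' @examples
#' partition_models(1, 1, c(0.25, 0.75))  # priors 0.25, 0.5, 0.25
#' @export
partition_models <- function(base_a, base_b, cutpoints = numeric(0)) {
  stopifnot(is.numeric(cutpoints))
  if (length(cutpoints)) {
    if (any(cutpoints <= 0 | cutpoints >= 1))
      stop("cutpoints must lie strictly inside (0, 1)", call. = FALSE)
    if (any(diff(cutpoints) <= 0))
      stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  bounds <- c(0, cutpoints, 1)
  models <- vector("list", length(bounds) - 1L)
  priors <- numeric(length(models))
  for (i in seq_along(models)) {
    l <- bounds[i]; u <- bounds[i + 1L]
    models[[i]] <- interval_model(base_a, base_b, l, u)
    priors[i] <- beta_interval_mass(base_a, base_b, l, u)
  }
  priors <- priors / sum(priors)
  model_set(models, prior_probs = priors)
}

#' Full model-comparison report
#'
#' Per-model log marginal likelihoods, prior and posterior model
#' probabilities, pairwise log Bayes factors, and the model-averaged
#' predictive success probability.
#'
#' @inheritParams posterior_model_probs
#' @return an object of class `comparison_report`: a list with elements
#'   `table` (data frame: label, log_marginal, prior_prob, posterior_prob),
#'   `log_bf` (antisymmetric matrix of pairwise log Bayes factors) and
#'   `bma_predictive`.
#' @export
compare_models <- function(model_set, data) {
  data <- as_binary_data(data)
  lm <- vapply(model_set$models, log_marginal, numeric(1), data = data)
  post <- posterior_model_probs(model_set, data)
  tab <- data.frame(label = model_set$labels,
                    log_marginal = lm,
                    prior_prob = model_set$prior_probs,
                    posterior_prob = as.numeric(post),
                    stringsAsFactors = FALSE)
  lbf <- outer(lm, lm, `-`)
  lbf[is.nan(lbf)] <- NA_real_   # -Inf minus -Inf: undefined ratio
  dimnames(lbf) <- list(model_set$labels, model_set$labels)
  structure(list(table = tab, log_bf = lbf,
                 bma_predictive = bma_predictive(model_set, data),
                 data = data),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  cat(sprintf("Model comparison on %s\n\n", format(x$data)))
  print(cbind(x$table[1], round(x$table[-1], digits)), row.names = FALSE)
  cat(sprintf("\nBMA predictive P(success) = %.*f\n", digits,
              x$bma_predictive))
  invisible(x)
}

#' Serialize a comparison report
#'
#' Writes the per-model table as CSV (one row per model) or the full report
#' as JSON.
#'
#' @param report a `comparison_report`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  stopifnot(inherits(report, "comparison_report"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(report$table, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(models = report$table,
           log_bayes_factors = report$log_bf,
           bma_predictive = report$bma_predictive,
           data = list(successes = report$data$s, failures = report$data$f)),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
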