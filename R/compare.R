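#' Fit a Bayesian model comparison to binary data
#'
#' The package's central fitting function. Given a set of Bernoulli models
#' and exchangeable binary data it computes, exactly and in closed form:
#' per-model log marginal likelihoods and pairwise log Bayes factors;
#' posterior model probabilities and the Bayesian-model-averaging (BMA)
#' predictive (when prior model probabilities are available); the exact
#' leave-one-out predictive table; stacking weights maximizing the average
#' log LOO score over the simplex, with the stacked predictive; and a
#' prequential order-invariance check when the data carry an order.
#'
#' @param models a [model_set], or a single `bern_model`.
#' @param data a [binary_data] object or a 0/1 vector.
#' @param prior_probs optional prior model probabilities overriding those in
#'   `models`.
#' @return an object of class `bern_compare` with components `models`,
#'   `data`, `log_marginal`, `comparison` (a [compare_models] report, or
#'   `NULL` without priors), `loo` (a [loo_table], or `NULL` when `n < 2`),
#'   `stacking` (a [stacking_weights] solution), `bma_predictive`,
#'   `stacking_predictive` and `prequential_deviation`.
#' @examples
#' fit <- bern_compare(partition_models(1, 1, c(0.25, 0.75)),
#'                     binary_data(successes = 10, failures = 10))
#' fit
#' coef(fit)
#' predict(fit, type = "stacking")
#' @seealso [run_scenario()] for the packaged worked examples.
#' @export
bern_compare <- function(models, data, prior_probs = NULL) {
  if (inherits(models, "bern_model"))
    models <- model_set(models, prior_probs = if (is.null(prior_probs)) 1)
  stopifnot(inherits(models, "model_set"))
  if (!is.null(prior_probs))
    models <- model_set(models$models, prior_probs = prior_probs)
  data <- as_binary_data(data)

  lm <- vapply(models$models, log_marginal, numeric(1), data = data)
  names(lm) <- models$labels

  comparison <- if (!is.null(models$prior_probs))
    compare_models(models, data) else NULL

  loo <- NULL; stack <- NULL; stack_pred <- NULL
  if (data$n >= 2L) {
    loo <- loo_table(models, data)
    if (any(loo$defined)) {
      stack <- withCallingHandlers(
        stacking_weights(loo),
        warning = function(w) invokeRestart("muffleWarning"))
      stack_pred <- stacking_predictive(stack, models, data)
    }
  }

  preq <- if (!is.null(data$outcomes)) {
    max(vapply(models$models, check_order_invariance, numeric(1),
               data = data, n_permutations = 10, seed = 7L))
  } else NA_real_

  structure(list(models = models, data = data, log_marginal = lm,
                 comparison = comparison, loo = loo, stacking = stack,
                 bma_predictive = if (is.null(comparison)) NULL else
                   comparison$bma_predictive,
                 stacking_predictive = stack_pred,
                 prequential_deviation = preq),
            class = "bern_compare")
}

#' @export
print.bern_compare <- function(x, digits = 4, ...) {
  cat(sprintf("Bayesian model comparison: %d model(s), %s\n",
              length(x$models$models), format(x$data)))
  tab <- data.frame(label = x$models$labels,
                    log_marginal = round(x$log_marginal, digits))
  if (!is.null(x$comparison))
    tab$posterior_prob <- round(x$comparison$table$posterior_prob, digits)
  if (!is.null(x$stacking))
    tab$stacking_weight <- round(x$stacking$weights, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$bma_predictive))
    cat(sprintf("BMA predictive P(success):      %.*f\n", digits,
                x$bma_predictive))
  if (!is.null(x$stacking_predictive))
    cat(sprintf("Stacking predictive P(success): %.*f\n", digits,
                x$stacking_predictive))
  invisible(x)
}

#' @export
summary.bern_compare <- function(object, digits = 4, ...) {
  print(object, digits = digits)
  if (!is.null(object$loo)) {
    cat("\nExact LOO predictive densities:\n")
    print(render_table1(object, digits = digits))
  }
  if (!is.null(object$stacking) && length(object$stacking$excluded))
    cat("\nExcluded from stacking (undefined LOO conditional):",
        paste(object$stacking$excluded, collapse = ", "), "\n")
  if (!is.na(object$prequential_deviation))
    cat(sprintf("\nPrequential order-invariance deviation: %.2e\n",
                object$prequential_deviation))
  invisible(object)
}

#' Extract model weights from a comparison fit
#'
#' Returns the per-model prior probabilities, posterior model probabilities
#' and stacking weights (those available) as a matrix with one row per
#' model.
#'
#' @param object a [bern_compare] fit.
#' @param ... unused.
#' @export
coef.bern_compare <- function(object, ...) {
  out <- NULL
  if (!is.null(object$models$prior_probs))
    out <- cbind(out, prior = object$models$prior_probs)
  if (!is.null(object$comparison))
    out <- cbind(out, posterior = object$comparison$table$posterior_prob)
  if (!is.null(object$stacking))
    out <- cbind(out, stacking = unname(object$stacking$weights))
  rownames(out) <- object$models$labels
  out
}

#' Predict the next observation from a comparison fit
#'
#' The probability that one new observation is a success, under either the
#' BMA predictive (posterior-model-probability weights) or the stacking
#' predictive (stacking weights).
#'
#' @param object a [bern_compare] fit.
#' @param type `"bma"` or `"stacking"`.
#' @param ... unused.
#' @return a probability in [0, 1].
#' @export
predict.bern_compare <- function(object, type = c("bma", "stacking"), ...) {
  type <- match.arg(type)
  p <- switch(type, bma = object$bma_predictive,
              stacking = object$stacking_predictive)
  if (is.null(p))
    stop(sprintf("%s predictive unavailable for this fit", type),
         call. = FALSE)
  p
}

#' Simulate new observations from the model-averaged predictive
#'
#' Draws `nsim` future binary observations, each independently from the
#' one-step predictive of the fit (BMA by default).
#'
#' @param object a [bern_compare] fit.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param type passed to [predict.bern_compare()].
#' @param ... unused.
#' @export
simulate.bern_compare <- function(object, nsim = 1, seed = NULL,
                                  type = "bma", ...) {
  p <- predict(object, type = type)
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
  }
  stats::rbinom(nsim, 1L, p)
}

#' Plot model-averaged posterior densities
#'
#' Draws the BMA posterior density of the Bernoulli rate (solid) and, when
#' available, the stacking-weighted mixture (dashed) over a theta grid.
#' Requires interval models (the other families have no density).
#'
#' @param x a [bern_compare] fit.
#' @param theta_grid evaluation grid in [0, 1].
#' @param ... passed to [graphics::plot()].
#' @export
plot.bern_compare <- function(x, theta_grid = seq(0, 1, length.out = 1001),
                              ...) {
  dens <- bma_posterior_density(x$models, x$data, theta_grid)
  graphics::plot(theta_grid, dens, type = "l", xlab = expression(theta),
                 ylab = "posterior density", ...)
  if (!is.null(x$stacking)) {
    sdens <- stacking_posterior_density(x$stacking, x$models, x$data,
                                        theta_grid)
    graphics::lines(theta_grid, sdens, lty = 2)
    graphics::legend("topright", legend = c("BMA", "stacking mixture"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
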