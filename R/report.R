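#' Run a packaged scenario end to end
#'
#' Builds the named [scenario()], fits it with [bern_compare()], and wraps
#' the result with the scenario configuration, package version and seed into
#' a self-describing run report. The computation is fully deterministic
#' given the configuration; the seed only pins the permutation draws of the
#' prequential order-invariance check.
#'
#' @param name a registered scenario name (see [list_scenarios()]).
#' @param n sample size where the scenario admits one.
#' @param seed integer seed recorded in the report.
#' @return an object of class `run_report`: list with `scenario`, `fit`
#'   (a [bern_compare]), `config` (the serializable model/data description),
#'   `version` and `seed`.
#' @examples
#' rep <- run_scenario("fig2_bernoulli")
#' render_table1(rep)
#' @export
run_scenario <- function(name, n = NULL, seed = 1L) {
  sc <- scenario(name, n = n)
  fit <- bern_compare(sc$models, sc$data)
  structure(list(scenario = sc$name, fit = fit,
                 config = list(models = lapply(sc$models$models,
                                               encode_model),
                               prior_probs = sc$models$prior_probs,
                               data = list(successes = sc$data$s,
                                           failures = sc$data$f)),
                 version = as.character(utils::packageVersion("bernstack")),
                 seed = as.integer(seed)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report for scenario '%s' (bernstack %s)\n\n",
              x$scenario, x$version))
  print(x$fit)
  invisible(x)
}

#' Tabulate exact LOO predictive densities
#'
#' Formats the leave-one-out predictive table as two rows (held-out value
#' 0 and 1) by one column per model, rounded half-to-even at the printed
#' precision.
#'
#' @param x a [loo_table], a [bern_compare] fit, or a [run_scenario] report.
#' @param digits decimals to round to (default 4).
#' @return a 2-row numeric matrix (`NA` where a value is absent from the
#'   data, so no held-out conditional exists).
#' @export
render_table1 <- function(x, digits = 4) {
  tab <- if (inherits(x, "loo_table")) x
  else if (inherits(x, "bern_compare")) x$loo
  else if (inherits(x, "run_report")) x$fit$loo
  else stop("cannot extract a LOO table from this object", call. = FALSE)
  if (is.null(tab)) stop("no LOO table available", call. = FALSE)
  out <- rbind(`y_i = 0` = round(tab$q0, digits),
               `y_i = 1` = round(tab$q1, digits))
  colnames(out) <- tab$model_label
  out
}

#' Serialize a run report to JSON
#'
#' Writes a deterministic, self-describing JSON document: the scenario
#' configuration echo, per-model log marginal likelihoods, posterior model
#' probabilities, the LOO table, stacking weights and both predictive
#' probabilities. Running the same configuration twice yields byte-identical
#' output.
#'
#' @param report a [run_scenario] report.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  fit <- report$fit
  doc <- list(
    scenario = report$scenario,
    version = report$version,
    seed = report$seed,
    config = report$config,
    log_marginal = as.list(fit$log_marginal),
    posterior_model_probs = if (is.null(fit$comparison)) NULL else
      as.list(stats::setNames(fit$comparison$table$posterior_prob,
                              fit$comparison$table$label)),
    loo = if (is.null(fit$loo)) NULL else as.data.frame(fit$loo),
    stacking = if (is.null(fit$stacking)) NULL else list(
      weights = as.list(fit$stacking$weights),
      objective_value = fit$stacking$objective_value,
      converged = fit$stacking$converged,
      flat_optimum = fit$stacking$flat_optimum),
    bma_predictive = fit$bma_predictive,
    stacking_predictive = fit$stacking_predictive,
    prequential_deviation = fit$prequential_deviation)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Serialize a LOO table to CSV
#'
#' One row per model with columns `model_label`, `q0`, `q1`, `defined`.
#'
#' @param table a [loo_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_loo_table <- function(table, path) {
  stopifnot(inherits(table, "loo_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
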