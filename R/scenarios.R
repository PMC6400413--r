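#' Generate an exchangeable Bernoulli sequence
#'
#' Seeded generator for synthetic binary outcome data with a fixed rate.
#' The same seed always yields the identical ordered sequence; the global
#' RNG state is restored afterwards.
#'
#' @param n number of observations (`n >= 0`).
#' @param theta success probability in [0, 1].
#' @param seed integer seed.
#' @return a [binary_data] with an ordered sequence of length `n`.
#' @examples
#' generate_bernoulli(20, 0.5, seed = 1)
#' @export
generate_bernoulli <- function(n, theta, seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == floor(n))
  if (!is.numeric(theta) || theta < 0 || theta > 1)
    stop("`theta` must lie in [0, 1]", call. = FALSE)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  binary_data(outcomes = stats::rbinom(n, 1L, theta))
}

# registry of the worked scenarios; each entry builds models + data
scenario_registry <- list(
  fig2_bernoulli = function(n = NULL) {
    list(models = partition_models(1, 1, c(0.25, 0.75)),
         data = binary_data(c(rep(1L, 10), rep(0L, 10))))
  },
  tumor_grid = function(n = NULL) {
    list(models = model_set(
      grid_model(values = 2^-(1:10), weights = rep(1 / 10, 10),
                 label = "tumor transplantability grid"),
      prior_probs = 1),
      data = binary_data(c(1L, rep(0L, 5))))
  },
  general_law = function(n = 2L) {
    stopifnot(n >= 2)
    list(models = model_set(
      point_model(1, label = "general law (theta = 1)"),
      interval_model(label = "unknown quantity (uniform)"),
      prior_probs = c(0.5, 0.5)),
      data = binary_data(rep(1L, n)))
  },
  single_failure = function(n = 20L) {
    stopifnot(n >= 2)
    list(models = model_set(
      point_model(1, label = "general law (theta = 1)"),
      interval_model(label = "unknown quantity (uniform)"),
      prior_probs = c(0.5, 0.5)),
      data = binary_data(c(rep(1L, n - 1L), 0L)))
  }
)

#' Worked example scenarios
#'
#' A registry of the small fixed scenarios used throughout the package
#' documentation and tests:
#' \describe{
#'   \item{`fig2_bernoulli`}{a uniform prior partitioned into three interval
#'     models at cutpoints .25 and .75 (prior probabilities .25/.5/.25),
#'     with 10 successes in n = 20 observations.}
#'   \item{`tumor_grid`}{tumor transplantability in mice: the take
#'     probability is `(1/2)^k` for `k = 1..10` genes, uniform prior over
#'     `k`; data are 1 take out of 6 attempts.}
#'   \item{`general_law`}{a point mass at theta = 1 ("all swans are white")
#'     versus a uniform alternative, with `n` all-success observations
#'     (default n = 2, two white swans).}
#'   \item{`single_failure`}{the same pair of models, with `n - 1` successes
#'     and one failure (default n = 20) — the single counterexample that
#'     falsifies the general law.}
#' }
#' Data are ordered with all successes before all failures, so prequential
#' traces are well defined.
#'
#' @param name a registered scenario name.
#' @param n sample size, where the scenario admits one (`general_law`,
#'   `single_failure`).
#' @return an object of class `scenario`: list with `name`, `models`
#'   (a [model_set]) and `data` (a [binary_data]).
#' @examples
#' scenario("fig2_bernoulli")
#' scenario("general_law", n = 10)
#' @export
scenario <- function(name, n = NULL) {
  if (!name %in% names(scenario_registry))
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(names(scenario_registry), collapse = ", ")),
         call. = FALSE)
  built <- if (is.null(n)) scenario_registry[[name]]()
           else scenario_registry[[name]](n = n)
  structure(c(list(name = name), built), class = "scenario")
}

#' @rdname scenario
#' @export
list_scenarios <- function() names(scenario_registry)

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s\n", x$name, format(x$data)))
  print(x$models)
  invisible(x)
}

#' Read and write model/data configurations
#'
#' A scenario (models plus data) serializes to a YAML document with a
#' `models` list — each entry an object with `type` (`point`, `interval`
#' or `grid`), `label` and type-specific fields — optional
#' `prior_probs`, and a `data` block given either as
#' `counts: {successes, failures}` or `sequence: [0, 1, ...]`.
#'
#' @param x a `scenario` or a list with elements `models` ([model_set]) and
#'   `data` ([binary_data]).
#' @param path file path.
#' @return `read_config` returns a list with `models` and `data` (and
#'   `name` when present); `write_config` returns `path` invisibly.
#' @export
write_config <- function(x, path) {
  stopifnot(inherits(x$models, "model_set"), inherits(x$data, "binary_data"))
  enc <- list(models = lapply(x$models$models, encode_model))
  if (!is.null(x$models$prior_probs))
    enc$prior_probs <- as.numeric(x$models$prior_probs)
  enc$data <- if (is.null(x$data$outcomes))
    list(counts = list(successes = x$data$s, failures = x$data$f))
  else list(sequence = as.integer(x$data$outcomes))
  if (!is.null(x$name)) enc$name <- x$name
  yaml::write_yaml(enc, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$models)) stop("config has no `models` block", call. = FALSE)
  models <- lapply(cfg$models, decode_model)
  ms <- model_set(models, prior_probs = cfg$prior_probs)
  if (!is.null(cfg$data$sequence)) {
    data <- binary_data(outcomes = as.integer(cfg$data$sequence))
  } else if (!is.null(cfg$data$counts)) {
    data <- binary_data(successes = cfg$data$counts$successes,
                        failures = cfg$data$counts$failures)
  } else stop("config has no `data` block", call. = FALSE)
  out <- list(models = ms, data = data)
  if (!is.null(cfg$name)) out$name <- cfg$name
  out
}

encode_model <- function(m) {
  if (inherits(m, "point_model"))
    list(type = "point", label = m$label, theta0 = m$theta0)
  else if (inherits(m, "interval_model"))
    list(type = "interval", label = m$label, base_a = m$base_a,
         base_b = m$base_b, lower = m$lower, upper = m$upper)
  else
    list(type = "grid", label = m$label,
         values = as.numeric(m$grid_values),
         weights = as.numeric(m$prior_weights))
}

decode_model <- function(spec) {
  switch(spec$type,
    point = point_model(spec$theta0, label = spec$label),
    interval = interval_model(spec$base_a, spec$base_b, spec$lower,
                              spec$upper, label = spec$label),
    grid = grid_model(unlist(spec$values), unlist(spec$weights),
                      label = spec$label),
    stop(sprintf("unknown model type '%s'", spec$type), call. = FALSE))
}
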