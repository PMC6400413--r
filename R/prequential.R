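#' Prequential (one-step-ahead) decomposition of the marginal likelihood
#'
#' The marginal likelihood factors exactly into one-step-ahead predictive
#' probabilities:
#' `p(y | M) = p(y1 | M) * p(y2 | y1, M) * ... * p(yn | y1..y_{n-1}, M)`.
#' This function computes each factor
#' `p(y_i | y_{1:(i-1)}, M)` for an explicitly ordered sequence, their
#' accumulated log product, and the directly computed log marginal, so the
#' identity can be checked. A factor of 0 (the model is falsified at step i)
#' makes all later conditionals undefined (`NA`) and the total `-Inf`.
#'
#' @param model a `bern_model`.
#' @param data a [binary_data] built from an ordered sequence.
#' @return an object of class `prequential_trace`: data frame with columns
#'   `index`, `y`, `factor`, `cum_log`, plus attributes `log_marginal_direct`
#'   and `log_marginal_accumulated`.
#' @examples
#' d <- binary_data(c(1, 1, 1, 0))
#' one_step_ahead(interval_model(), d)
#' @export
one_step_ahead <- function(model, data) {
  data <- as_binary_data(data)
  if (is.null(data$outcomes))
    stop("prequential decomposition needs an explicitly ordered sequence",
         call. = FALSE)
  y <- data$outcomes
  n <- length(y)
  fac <- rep(NA_real_, n)
  cum <- rep(NA_real_, n)
  lm_prefix <- log_marginal(model, binary_data(successes = 0, failures = 0))
  total <- 0
  for (i in seq_len(n)) {
    if (lm_prefix == -Inf) break   # conditioning on probability-0 prefix
    prefix <- binary_data(successes = sum(y[seq_len(i)] == 1L) -
                            (y[i] == 1L),
                          failures = sum(y[seq_len(i)] == 0L) -
                            (y[i] == 0L))
    lm_next <- log_marginal(model, binary_data(
      successes = prefix$s + (y[i] == 1L),
      failures = prefix$f + (y[i] == 0L)))
    fac[i] <- exp(lm_next - lm_prefix)
    total <- if (fac[i] == 0) -Inf else total + log(fac[i])
    cum[i] <- total
    lm_prefix <- lm_next
  }
  if (any(is.na(fac))) total <- -Inf
  out <- data.frame(index = seq_len(n), y = y, factor = fac, cum_log = cum)
  structure(out, class = c("prequential_trace", "data.frame"),
            log_marginal_accumulated = total,
            log_marginal_direct = log_marginal(model, data))
}

#' @export
print.prequential_trace <- function(x, ...) {
  cat("One-step-ahead predictive trace\n")
  print.data.frame(x)
  cat(sprintf("accumulated log product: %g\ndirect log marginal:     %g\n",
              attr(x, "log_marginal_accumulated"),
              attr(x, "log_marginal_direct")))
  invisible(x)
}

#' Serialize a prequential trace to CSV
#'
#' @param trace a [one_step_ahead] trace.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "prequential_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Order invariance of the accumulated marginal likelihood
#'
#' For exchangeable models the prequential product cannot depend on the
#' order in which observations are processed. This check accumulates the
#' one-step-ahead log product under random permutations of the sequence and
#' returns the maximum absolute deviation across permutations (0 when every
#' permutation yields `-Inf`, as for a falsified point model).
#'
#' @param model a `bern_model`.
#' @param data a [binary_data] with an ordered sequence.
#' @param n_permutations number of random permutations (default 20; the
#'   identity is exact, so more adds nothing).
#' @param seed integer seed for the permutation draws.
#' @return maximum absolute deviation of accumulated log marginals.
#' @export
check_order_invariance <- function(model, data, n_permutations = 20,
                                   seed = 1L) {
  data <- as_binary_data(data)
  if (is.null(data$outcomes))
    stop("order invariance needs an ordered sequence", call. = FALSE)
  stopifnot(n_permutations >= 1)
  y <- data$outcomes
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  totals <- vapply(seq_len(n_permutations), function(j) {
    perm <- sample(y)
    attr(one_step_ahead(model, binary_data(perm)),
         "log_marginal_accumulated")
  }, numeric(1))
  totals <- c(totals,
              attr(one_step_ahead(model, data), "log_marginal_accumulated"))
  if (all(totals == -Inf)) return(0)
  max(totals) - min(totals)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
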