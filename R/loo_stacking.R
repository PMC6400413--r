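#' Exact leave-one-out predictive densities
#'
#' For exchangeable binary data the leave-one-out (LOO) predictive density
#' of observation i depends only on its value, not its position: each model
#' contributes one pair `(q0, q1)` with
#' `q_v = p(y_i = v | y_-i, M) = p(y | M) / p(y_-i | M)`,
#' a ratio of marginal likelihoods — no refitting needed. A value that does
#' not occur in the data has no held-out conditional and its entry is `NA`.
#' A model under which some reduced data set `y_-i` has probability zero
#' (so the conditional is 0/0) is flagged `defined = FALSE`.
#'
#' @param models a [model_set].
#' @param data a [binary_data] object with `n >= 2`.
#' @return an object of class `loo_table`: a data frame with columns
#'   `model_label`, `q0`, `q1`, `defined`, one row per model, carrying the
#'   data counts as attributes.
#' @examples
#' ms <- partition_models(1, 1, c(0.25, 0.75))
#' loo_table(ms, binary_data(successes = 10, failures = 10))
#' @export
loo_table <- function(models, data) {
  stopifnot(inherits(models, "model_set"))
  data <- as_binary_data(data)
  if (data$n < 2L)
    stop("leave-one-out needs at least 2 observations", call. = FALSE)
  rows <- lapply(models$models, function(m) {
    lm_full <- log_marginal(m, data)
    q <- c(NA_real_, NA_real_)   # (q0, q1)
    defined <- TRUE
    if (data$f >= 1L) {
      lm_red <- log_marginal(m, augment_data(data, add_f = -1L))
      if (lm_red == -Inf) defined <- FALSE else q[1] <- exp(lm_full - lm_red)
    }
    if (data$s >= 1L) {
      lm_red <- log_marginal(m, augment_data(data, add_s = -1L))
      if (lm_red == -Inf) defined <- FALSE else q[2] <- exp(lm_full - lm_red)
    }
    list(q0 = q[1], q1 = q[2], defined = defined)
  })
  tab <- data.frame(model_label = models$labels,
                    q0 = vapply(rows, `[[`, numeric(1), "q0"),
                    q1 = vapply(rows, `[[`, numeric(1), "q1"),
                    defined = vapply(rows, `[[`, logical(1), "defined"),
                    stringsAsFactors = FALSE)
  structure(tab, class = c("loo_table", "data.frame"),
            s = data$s, f = data$f, n = data$n)
}

#' Weighted LOO predictive density of a single observation
#'
#' The inner sum of the stacking objective:
#' `sum_k w_k * p(y_i = value | y_-i, M_k)`.
#'
#' @param weights simplex weight vector over the models of `table`.
#' @param table a [loo_table].
#' @param value the held-out value, 0 or 1.
#' @return a number in [0, 1].
#' @export
combined_loo_density <- function(weights, table, value) {
  stopifnot(inherits(table, "loo_table"), value %in% c(0, 1))
  check_simplex(weights, nrow(table))
  q <- if (value == 0) table$q0 else table$q1
  active <- weights > 0
  if (any(active & !table$defined))
    stop("positive weight on a model with an undefined LOO conditional",
         call. = FALSE)
  if (any(active & is.na(q)))
    stop(sprintf("value %d does not occur in the data; its LOO density is %s",
                 value, "not defined"), call. = FALSE)
  sum(weights[active] * q[active])
}

#' Stacking objective (average log LOO score)
#'
#' The quantity stacking maximizes over the weight simplex: the average over
#' observations of the log of the weighted LOO predictive density,
#' `(1/n) * (f * log(sum_k w_k q0_k) + s * log(sum_k w_k q1_k))`.
#' Returns `-Inf` when a weighted density needed by the data is 0.
#'
#' @inheritParams combined_loo_density
#' @param data the [binary_data] the table was computed from (supplies the
#'   counts; defaults to the counts stored in the table).
#' @return a real number or `-Inf`.
#' @export
stacking_objective <- function(weights, table, data = NULL) {
  stopifnot(inherits(table, "loo_table"))
  counts <- if (is.null(data)) {
    c(f = attr(table, "f"), s = attr(table, "s"))
  } else {
    data <- as_binary_data(data)
    c(f = data$f, s = data$s)
  }
  n <- sum(counts)
  obj <- 0
  for (v in c(0, 1)) {
    cnt <- if (v == 0) counts[["f"]] else counts[["s"]]
    if (cnt == 0) next
    dens <- combined_loo_density(weights, table, v)
    if (dens <= 0) return(-Inf)
    obj <- obj + cnt * log(dens)
  }
  obj / n
}

#' Stacking weights by maximizing the LOO log score on the simplex
#'
#' Maximizes the concave stacking objective over the probability simplex by
#' multiplicative (EM-style) updates, which keep iterates on the simplex and
#' approach boundary optima (weights exactly 0 or 1) asymptotically. After
#' convergence, weights below 1e-6 are snapped to 0 and the vector is
#' renormalized, provided the snap costs less than 1e-10 in objective.
#'
#' Models with an undefined LOO conditional (some `y_-i` has probability 0
#' under the model, so the held-out conditional is 0/0) are excluded from
#' the simplex with weight fixed at 0 and a warning: any positive weight on
#' such a model is dominated.
#'
#' The optimum need not identify the weights: duplicated or
#' linearly-redundant predictive rows leave the objective flat along a face
#' of the simplex. `flat_optimum` is set when perturbing the solution 1e-3
#' of the way toward some vertex changes the objective by less than 1e-10;
#' only the combined predictive density is identified in that case.
#'
#' @param table a [loo_table].
#' @param data optional [binary_data] (counts default to those in `table`).
#' @param max_iter,tol_obj,tol_w convergence controls: iteration cap,
#'   minimum objective improvement and minimum weight change.
#' @return an object of class `stacking_solution`: list with `weights`
#'   (full-length, zeros for excluded models), `objective_value`,
#'   `converged`, `flat_optimum`, `excluded` (labels of excluded models)
#'   and `iterations`.
#' @examples
#' ms <- partition_models(1, 1, c(0.25, 0.75))
#' tab <- loo_table(ms, binary_data(successes = 10, failures = 10))
#' stacking_weights(tab)
#' @export
stacking_weights <- function(table, data = NULL, max_iter = 1e5,
                             tol_obj = 1e-12, tol_w = 1e-8) {
  stopifnot(inherits(table, "loo_table"))
  counts <- if (is.null(data)) {
    c(f = attr(table, "f"), s = attr(table, "s"))
  } else {
    data <- as_binary_data(data)
    c(f = data$f, s = data$s)
  }
  n <- sum(counts)
  M <- nrow(table)
  feasible <- which(table$defined)
  if (length(feasible) == 0L)
    stop("no model has a defined LOO conditional; stacking is infeasible",
         call. = FALSE)
  if (length(feasible) < M)
    warning(sprintf(
      "excluding model(s) with undefined LOO conditionals: %s",
      paste(table$model_label[-feasible], collapse = ", ")), call. = FALSE)

  # per-value predictive matrix restricted to the feasible models and to
  # the values that actually occur (each row: one value, with its count)
  vals <- c(0, 1)[c(counts[["f"]] > 0, counts[["s"]] > 0)]
  Q <- rbind(if (counts[["f"]] > 0) table$q0[feasible],
             if (counts[["s"]] > 0) table$q1[feasible])
  cnt <- c(if (counts[["f"]] > 0) counts[["f"]],
           if (counts[["s"]] > 0) counts[["s"]])

  obj_of <- function(w) {
    dens <- as.numeric(Q %*% w)
    if (any(dens <= 0)) return(-Inf)
    sum(cnt * log(dens)) / n
  }

  w <- rep(1 / length(feasible), length(feasible))
  obj <- obj_of(w)
  if (obj == -Inf)
    stop("stacking objective is degenerate (weighted LOO density 0 at the ",
         "interior starting point)", call. = FALSE)
  converged <- FALSE
  iter <- 0L
  if (length(feasible) > 1L) {
    for (iter in seq_len(max_iter)) {
      dens <- as.numeric(Q %*% w)
      grad <- as.numeric(crossprod(Q, cnt / dens)) / n   # d obj / d w_k
      w_new <- w * grad
      w_new <- w_new / sum(w_new)
      obj_new <- obj_of(w_new)
      dw <- max(abs(w_new - w))
      improved <- obj_new - obj
      w <- w_new; obj <- obj_new
      if (improved < tol_obj && dw < tol_w) { converged <- TRUE; break }
    }
  } else converged <- TRUE

  # snap near-zero weights to exact 0 when it costs (numerically) nothing
  snap <- w < 1e-6
  if (any(snap) && !all(snap)) {
    w_snap <- ifelse(snap, 0, w)
    w_snap <- w_snap / sum(w_snap)
    if (obj_of(w_snap) >= obj - 1e-10) { w <- w_snap; obj <- obj_of(w) }
  }

  # flatness probe: transfer 1e-3 of weight along each edge of the simplex;
  # an edge along which the objective moves by < 1e-10 (e.g. between
  # duplicated models) means the weights are not identified
  flat <- FALSE
  eps <- 1e-3
  for (j in seq_along(w)) {
    if (w[j] < eps) next
    for (k in seq_along(w)) {
      if (k == j) next
      w_pert <- w; w_pert[j] <- w_pert[j] - eps; w_pert[k] <- w_pert[k] + eps
      if (abs(obj_of(w_pert) - obj) < 1e-10) { flat <- TRUE; break }
    }
    if (flat) break
  }

  weights <- numeric(M)
  weights[feasible] <- w
  names(weights) <- table$model_label
  structure(list(weights = weights, objective_value = obj,
                 converged = converged, flat_optimum = flat,
                 excluded = table$model_label[setdiff(seq_len(M), feasible)],
                 iterations = iter),
            class = "stacking_solution")
}

#' @export
print.stacking_solution <- function(x, digits = 4, ...) {
  cat("Stacking solution\n  weights:\n")
  for (k in seq_along(x$weights))
    cat(sprintf("    %-30s %.*f\n", names(x$weights)[k], digits,
                x$weights[k]))
  cat(sprintf("  objective (mean log LOO density): %.6f\n",
              x$objective_value))
  if (length(x$excluded))
    cat("  excluded (undefined LOO conditional):",
        paste(x$excluded, collapse = ", "), "\n")
  if (x$flat_optimum)
    cat("  note: flat optimum; weights are not identified\n")
  invisible(x)
}

#' Stacking-weighted predictive probability of a success
#'
#' `sum_k w_k * p(y_new = 1 | y, M_k)` under the stacking weights. Models
#' with weight 0 are skipped, so excluded (falsified) models do not need a
#' defined predictive.
#'
#' @param solution a [stacking_weights] solution.
#' @param models the [model_set] the solution was computed for.
#' @param data a [binary_data] object.
#' @return a probability in [0, 1].
#' @export
stacking_predictive <- function(solution, models, data) {
  stopifnot(inherits(solution, "stacking_solution"),
            inherits(models, "model_set"))
  data <- as_binary_data(data)
  w <- unname(solution$weights)
  stopifnot(length(w) == length(models$models))
  p <- 0
  for (k in seq_along(w)) {
    if (w[k] == 0) next
    p <- p + w[k] * predictive_success(models$models[[k]], data)
  }
  p
}

#' Stacking-weighted mixture of posterior densities
#'
#' Mixes the per-model truncated posterior densities using the stacking
#' weights. This construction is illustrative: stacking weights are defined
#' for combining predictive distributions, and their proponents do not
#' suggest averaging parameter posteriors with them; the mixture is provided
#' to show what such an average would look like.
#'
#' @inheritParams stacking_predictive
#' @param theta_grid evaluation points in [0, 1].
#' @return density values on `theta_grid`.
#' @export
stacking_posterior_density <- function(solution, models, data,
                                       theta_grid = seq(0, 1, length.out = 1001)) {
  stopifnot(inherits(solution, "stacking_solution"),
            inherits(models, "model_set"))
  data <- as_binary_data(data)
  w <- unname(solution$weights)
  dens <- numeric(length(theta_grid))
  for (k in seq_along(w)) {
    if (w[k] == 0) next
    dens <- dens + w[k] *
      posterior_density(models$models[[k]], data, theta_grid)
  }
  dens
}

check_simplex <- function(w, m, tol = 1e-8) {
  if (length(w) != m)
    stop(sprintf("expected %d weights, got %d", m, length(w)), call. = FALSE)
  if (any(w < -tol) || abs(sum(w) - 1) > tol)
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  invisible(TRUE)
}
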