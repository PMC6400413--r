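#' Exchangeable binary outcome data
#'
#' Container for an exchangeable sequence of Bernoulli outcomes. Data may be
#' supplied either as an ordered 0/1 sequence (needed for prequential,
#' one-step-ahead computations) or as success/failure counts only, in which
#' case the ordering is unspecified.
#'
#' @param outcomes optional integer/numeric vector with values in \{0, 1\},
#'   the observations in the order they arrived.
#' @param successes,failures nonnegative integer counts; ignored when
#'   `outcomes` is given (they are then derived from the sequence).
#' @return An object of class `binary_data` with components `outcomes`
#'   (or `NULL`), `s` (successes), `f` (failures) and `n = s + f`.
#' @examples
#' binary_data(successes = 10, failures = 10)
#' binary_data(c(1, 1, 0, 1))
#' @export
binary_data <- function(outcomes = NULL, successes = NULL, failures = NULL) {
  if (!is.null(outcomes)) {
    if (length(outcomes) > 0 && !all(outcomes %in% c(0, 1)))
      stop("`outcomes` must contain only 0s and 1s", call. = FALSE)
    outcomes <- as.integer(outcomes)
    s <- sum(outcomes == 1L)
    f <- sum(outcomes == 0L)
  } else {
    if (is.null(successes) || is.null(failures))
      stop("supply either `outcomes` or both `successes` and `failures`",
           call. = FALSE)
    s <- as.integer(successes)
    f <- as.integer(failures)
    if (length(s) != 1L || length(f) != 1L || is.na(s) || is.na(f) ||
        s < 0L || f < 0L)
      stop("`successes` and `failures` must be single nonnegative integers",
           call. = FALSE)
  }
  structure(list(outcomes = outcomes, s = s, f = f, n = s + f),
            class = "binary_data")
}

#' @export
print.binary_data <- function(x, ...) {
  cat(sprintf("Binary outcome data: n = %d (%d successes, %d failures)%s\n",
              x$n, x$s, x$f,
              if (is.null(x$outcomes)) ", order unspecified" else ", ordered"))
  invisible(x)
}

#' @export
format.binary_data <- function(x, ...) {
  sprintf("binary_data(s = %d, f = %d)", x$s, x$f)
}

# internal: shift counts by extra observations (data "plus one success" etc.)
augment_data <- function(data, add_s = 0L, add_f = 0L) {
  binary_data(successes = data$s + add_s, failures = data$f + add_f)
}

as_binary_data <- function(x) {
  if (inherits(x, "binary_data")) return(x)
  if (is.numeric(x)) return(binary_data(outcomes = x))
  stop("cannot interpret object as binary outcome data", call. = FALSE)
}
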