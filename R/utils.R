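# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("densitycal_invalid_argument", "densitycal_error")))
}

stop_estimation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("densitycal_estimation_error", "densitycal_error")))
}

stop_infeasible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("densitycal_infeasible_error", "densitycal_error")))
}

signal_undefined <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c("densitycal_undefined_result", "densitycal_warning")))
  NA_real_
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    stop_invalid("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

#' Derive reproducible child seeds from a master seed
#'
#' All iteration-level randomness in the framework runners flows from a single
#' master seed through this function, so that a run is bit-reproducible and
#' iterations are mutually independent streams.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
child_seeds <- function(seed, n) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n, "n", positive = TRUE)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n, replace = FALSE))
}
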