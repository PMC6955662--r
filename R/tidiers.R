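# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a randomization-test result
#'
#' @param x An `sced_test`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `observed`, `p_value`, `tail`,
#'   `R`, `method`, `alpha`, `reject`.
#' @method tidy sced_test
#' @export
tidy.sced_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic_name,
    observed = x$observed,
    p_value = x$p_value,
    tail = x$tail,
    R = x$R,
    method = x$method,
    alpha = x$alpha,
    reject = x$reject
  )
}

#' Summarize a randomization-test run
#'
#' @param x An `sced_test`.
#' @param ... Unused.
#' @return A one-row tibble with the reference-set bookkeeping: `R`,
#'   `n_values`, `method`, `n_mc`, `seed`, `minimal_p`.
#' @method glance sced_test
#' @export
glance.sced_test <- function(x, ...) {
  tibble::tibble(
    R = x$R,
    n_values = x$n_values,
    method = x$method,
    n_mc = x$n_mc,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed),
    minimal_p = 1 / x$R
  )
}

#' Tidy a reference distribution
#'
#' @param x An `sced_reference`.
#' @param ... Unused.
#' @return A tibble with one row per reference assignment: `value` and
#'   `is_observed` (whether the value ties the observed statistic).
#' @method tidy sced_reference
#' @export
tidy.sced_reference <- function(x, ...) {
  tibble::tibble(
    value = x$values,
    is_observed = ge_tol(x$values, x$observed) & le_tol(x$values, x$observed)
  )
}

#' Tidy a power estimate
#'
#' @param x An `sced_power_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `power`, `mc_stderr`, `rejections`, `n_sims`,
#'   `alpha`, plus the effect-model parameters.
#' @method tidy sced_power_estimate
#' @export
tidy.sced_power_estimate <- function(x, ...) {
  tibble::tibble(
    power = x$power,
    mc_stderr = x$mc_stderr,
    rejections = x$rejections,
    n_sims = x$n_sims,
    alpha = x$alpha,
    delta = if (is.null(names(x$effect$delta))) x$effect$delta[1] else NA_real_,
    sd = x$effect$sd,
    ar1 = x$effect$ar1,
    R = x$R,
    method = x$method
  )
}

#' Summarize a power estimate
#'
#' @param x An `sced_power_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `R`, `minimal_p`, `nonzero_power`, `method`,
#'   `seed`.
#' @method glance sced_power_estimate
#' @export
glance.sced_power_estimate <- function(x, ...) {
  tibble::tibble(
    R = x$R,
    minimal_p = 1 / x$R,
    nonzero_power = has_nonzero_power(x$R, x$alpha),
    method = x$method,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}
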