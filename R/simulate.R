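# Synthetic SCED series with known structure: a level-shift model with
# Gaussian noise, optional per-phase linear trend, and lag-1 autocorrelated
# errors. Randomization tests are distribution-free, so the generator's job
# is controlled structure for validation and power studies, not realism.

#' Effect model for synthetic series
#'
#' The generating model is
#' `y_t = mu + shift(label_t) + trend * (j_t - 1) + e_t`,
#' where `j_t` is the occasion's position within its phase and the errors
#' follow a stationary AR(1) process: `e_t = ar1 * e_{t-1} + w_t` with
#' `w_t ~ N(0, sd^2 * (1 - ar1^2))`, so the marginal error sd equals `sd`
#' for every `ar1` (power comparisons across autocorrelation levels hold
#' the marginal noise constant).
#'
#' @param mu Baseline level (A-role occasions).
#' @param delta Treatment effect: a single shift applied to B-role
#'   occasions, or a named numeric vector of per-label shifts for designs
#'   with more than two conditions (labels absent from the vector shift by
#'   0).
#' @param sd Marginal noise standard deviation (>= 0).
#' @param ar1 Lag-1 autocorrelation of the errors, in (-1, 1).
#' @param trend Linear slope within each phase (scalar, applied to every
#'   phase), default 0.
#' @param ccd_adherence_sd Noise sd around the phase criterion used by
#'   [generate_ccd_series()].
#' @return An object of class `sced_effect_model`.
#' @examples
#' effect_model(mu = 50, delta = 10, sd = 5)
#' @export
effect_model <- function(mu = 0, delta = 1, sd = 1, ar1 = 0, trend = 0,
                         ccd_adherence_sd = 1) {
  if (sd < 0) abort_invalid("sd must be >= 0")
  if (abs(ar1) >= 1) abort_invalid("ar1 must lie strictly inside (-1, 1)")
  if (ccd_adherence_sd < 0) abort_invalid("ccd_adherence_sd must be >= 0")
  structure(list(mu = mu, delta = delta, sd = sd, ar1 = ar1, trend = trend,
                 ccd_adherence_sd = ccd_adherence_sd),
            class = "sced_effect_model")
}

# stationary AR(1) errors with marginal sd `sd`
ar1_errors <- function(n, sd, phi) {
  if (sd == 0) return(rep(0, n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1 && phi != 0) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (t in 2:n) e[t] <- phi * e[t - 1] + innov[t - 1]
  } else if (n > 1) {
    e[2:n] <- stats::rnorm(n - 1, 0, sd)
  }
  e
}

# per-label level shift; scalar delta means "B role shifts by delta"
label_shift <- function(labels, delta, b_labels = "B") {
  if (is.null(names(delta))) {
    ifelse(labels %in% b_labels, delta[1], 0)
  } else {
    out <- delta[labels]
    out[is.na(out)] <- 0
    unname(out)
  }
}

#' Generate a synthetic series under a design and assignment
#'
#' Draws one series (or one per unit for multiple baseline designs) from
#' the [effect_model()]: baseline occasions at level `mu`, treatment-role
#' occasions shifted by `delta`, an optional within-phase linear trend, and
#' stationary AR(1) Gaussian errors. Identical seeds and parameters yield
#' bit-identical series.
#'
#' @param design A design object (phase, alternation, or multiple baseline
#'   family; use [generate_ccd_series()] for changing criterion designs).
#' @param assignment An admissible assignment (labels or change points;
#'   start points for multiple baseline designs).
#' @param model An [effect_model()].
#' @param seed Optional integer seed.
#' @param b_labels Labels receiving the scalar `delta` shift (default "B").
#' @return A series tibble (`unit`, `occasion`, `value`).
#' @examples
#' d <- phase_design(c("A", "B", "A", "B"), 24, 3)
#' generate_series(d, c(7, 13, 19), effect_model(mu = 50, delta = 10, sd = 5),
#'                 seed = 1)
#' @export
generate_series <- function(design, assignment, model = effect_model(),
                            seed = NULL, b_labels = "B") {
  validate_design(design)
  if (!inherits(model, "sced_effect_model")) abort_invalid("model must be an effect_model()")
  assignment <- normalize_assignment(design, assignment)
  if (!is_admissible(design, assignment)) {
    abort_invalid("assignment is not admissible under the design")
  }
  with_seed(seed, {
    if (design$family == "mbd") {
      w <- design$start_window
      series <- lapply(seq_len(design$n_units), function(u) {
        labels <- c(rep("A", assignment[u] - 1L),
                    rep("B", design$n - assignment[u] + 1L))
        one_series(labels, model, b_labels)
      })
      names(series) <- paste0("unit", seq_len(design$n_units))
      sced_series(series)
    } else {
      labels <- to_labels(design, assignment)
      sced_series(one_series(labels, model, b_labels))
    }
  })
}

one_series <- function(labels, model, b_labels) {
  n <- length(labels)
  runs <- rle(labels)
  within_phase <- unlist(lapply(runs$lengths, seq_len), use.names = FALSE)
  model$mu + label_shift(labels, model$delta, b_labels) +
    model$trend * (within_phase - 1) + ar1_errors(n, model$sd, model$ar1)
}

#' Generate a synthetic changing-criterion series
#'
#' Emulates a participant tracking a stepwise criterion schedule: every
#' occasion's value is its phase criterion (the midpoint for range-bound
#' criteria) plus independent Gaussian noise of sd `ccd_adherence_sd`;
#' baseline occasions sit at the baseline criterion (the design's fixed
#' baseline value if set, otherwise the model's `mu`).
#'
#' @param design A `sced_ccd_design`.
#' @param change_points Admissible per-boundary change points.
#' @param model An [effect_model()] (only `ccd_adherence_sd` and `mu` are
#'   used).
#' @param seed Optional integer seed.
#' @return A series tibble.
#' @export
generate_ccd_series <- function(design, change_points, model = effect_model(),
                                seed = NULL) {
  validate_design(design)
  if (design$family != "ccd") abort_invalid("design must be a changing criterion design")
  change_points <- as.integer(change_points)
  if (!is_admissible(design, change_points)) {
    abort_invalid("change points are not admissible under the design")
  }
  base_value <- if (design$baseline_criterion == "fixed") {
    design$baseline_value
  } else {
    model$mu
  }
  k <- length(design$phase_labels)
  n <- design$n
  targets <- c(base_value, (design$criteria$lower + design$criteria$upper) / 2)
  phase_of <- rep(seq_len(k), times = diff(c(1L, change_points, n + 1L)))
  with_seed(seed, {
    values <- targets[phase_of] + stats::rnorm(n, 0, model$ccd_adherence_sd)
    sced_series(values)
  })
}
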