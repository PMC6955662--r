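# ggplot2 graphics: the reference-distribution histogram with the observed
# statistic marked, and the standard SCED time-series panel with phase
# changes.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reference distribution
#'
#' Histogram of the reference statistics with a vertical line at the
#' observed value — the standard display for locating an observed
#' randomization statistic in its reference distribution.
#'
#' @param object An `sced_reference`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sced_reference
#' @export
autoplot.sced_reference <- function(object, bins = 30, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = paste0(object$statistic$name, " (observed in red)"),
      y = "number of assignments",
      title = paste0("Reference distribution (",
                     if (object$method == "exhaustive") "exhaustive" else "Monte Carlo",
                     ", ", length(object$values), " values)")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sced_reference
#' @method autoplot sced_test
#' @export
autoplot.sced_test <- function(object, bins = 30, ...) {
  ref <- attr(object, "reference")
  if (is.null(ref)) abort_invalid("this sced_test carries no reference distribution")
  autoplot(ref, bins = bins, ...)
}

#' Plot a measurement series with its condition structure
#'
#' One panel per unit; points joined in occasion order, coloured by
#' condition label when an assignment is supplied, with dashed vertical
#' lines at phase changes.
#'
#' @param data A series tibble.
#' @param labels Optional per-occasion labels (single-unit data) marking
#'   conditions.
#' @param start_points Optional per-unit start occasions (multiple baseline
#'   data).
#' @return A ggplot.
#' @export
plot_series <- function(data, labels = NULL, start_points = NULL) {
  data <- validate_series(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$occasion, y = .data$value))
  if (!is.null(labels)) {
    labels <- string_to_labels(labels)
    data$condition <- labels[data$occasion]
    cps <- changepoints_from_labels(labels)
    p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$occasion, y = .data$value,
                                            colour = .data$condition)) +
      ggplot2::geom_vline(xintercept = cps - 0.5, linetype = "dashed",
                          colour = "grey50")
  }
  if (!is.null(start_points)) {
    units <- unique(data$unit)
    vl <- tibble::tibble(unit = units, cp = as.numeric(start_points) - 0.5)
    p <- p + ggplot2::geom_vline(data = vl, ggplot2::aes(xintercept = .data$cp),
                                 linetype = "dashed", colour = "grey50")
  }
  p +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~unit, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "measurement occasion", y = "value") +
    ggplot2::theme_minimal()
}
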