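#' Plot a monthly outcome series
#'
#' Scatter plot of a monthly series with an optional loess smoothing curve.
#' Smoothing is presentation only: trend verdicts always come from
#' [mann_kendall()] on the raw monthly values, never from the curve.
#'
#' @param series An `esm_series` tibble from [monthly_series()].
#' @param smooth Add a loess curve (default `TRUE`).
#' @param span Loess span.
#' @return A ggplot object.
#' @export
plot_monthly_trend <- function(series, smooth = TRUE, span = 0.4) {
  stopifnot(is.data.frame(series), all(c("month_index", "value") %in% names(series)))
  lab <- attr(series, "outcome") %||% "value"
  stat <- attr(series, "statistic") %||% ""
  p <- ggplot2::ggplot(
    series,
    ggplot2::aes(x = 1990 + .data$month_index / 12, y = .data$value)
  ) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(
      x = "year",
      y = paste(stat, lab),
      title = paste("Monthly", stat, "of", lab)
    ) +
    ggplot2::theme_minimal()
  if (smooth && nrow(series) >= 10) {
    p <- p + ggplot2::geom_smooth(
      method = "loess", span = span, se = FALSE, formula = y ~ x,
      linewidth = 0.7, colour = "firebrick"
    )
  }
  p
}

#' @rdname plot_monthly_trend
#' @param object,... Passed through (`autoplot` method for `esm_series`).
#' @exportS3Method ggplot2::autoplot
autoplot.esm_series <- function(object, ...) plot_monthly_trend(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot detected effect-size distribution by period
#'
#' Histogram of standardized effect sizes (linear scale) per period, the
#' tabular backbone of the "concentration near 1" displays.
#'
#' @param summaries Summary tibble from [condense_abstracts()].
#' @param outcome Outcome column to display (default `es_mean`).
#' @param breaks_years Period width in years (default 5).
#' @return A ggplot object.
#' @export
plot_es_distribution <- function(summaries, outcome = "es_mean",
                                 breaks_years = 5) {
  stopifnot(outcome %in% names(summaries))
  dat <- summaries[!is.na(summaries$month_index), ]
  dat$period <- paste0(
    1990 + (dat$month_index %/% (12 * breaks_years)) * breaks_years, "s"
  )
  ggplot2::ggplot(
    dat, ggplot2::aes(x = .data[[outcome]], colour = .data$period)
  ) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10(limits = c(1, 100)) +
    ggplot2::labs(
      x = paste(outcome, "(standardized, linear scale)"), y = "density"
    ) +
    ggplot2::theme_minimal()
}
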