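# ggplot2 views of the result objects.

#' @rdname autoplot_seastrat
#' @export
autoplot.density_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$density, y = .data$cum_fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(paste("Density (individuals ", m^-2, ")")),
                  y = "Cumulative proportion of counted individuals") +
    ggplot2::theme_minimal()
}

#' Plots of survey results
#'
#' `autoplot()` methods: a `density_curve` draws the cumulative concentration
#' curve; a `population_estimate` draws its per-stratum partial totals with
#' standard-error bars, faceted by survey domain.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot_seastrat
#' @export
autoplot.population_estimate <- function(object, ...) {
  b <- object$breakdown
  if (is.null(b)) {
    abort("estimate carries no per-stratum breakdown to plot")
  }
  ggplot2::ggplot(b, ggplot2::aes(x = .data$area_label,
                                  y = .data$partial_total / 1e6,
                                  fill = .data$depth_label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$partial_total - .data$partial_se, 0) / 1e6,
                   ymax = (.data$partial_total + .data$partial_se) / 1e6),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "Partial total (millions)", fill = "Depth (m)") +
    ggplot2::theme_minimal()
}

#' Plot an occurrence profile
#'
#' Bar chart of the frequency of occurrence per group with binomial
#' standard-error bars.
#'
#' @param profile A tibble from [occurrence_frequency()].
#' @param group Name of the grouping column to put on the x axis (defaults to
#'   the first column).
#' @return A ggplot.
#' @export
plot_occurrence <- function(profile, group = names(profile)[1]) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data[[group]], y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$proportion - .data$se, 0),
                   ymax = pmin(.data$proportion + .data$se, 1)),
      width = 0.2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Frequency of occurrence") +
    ggplot2::theme_minimal()
}
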