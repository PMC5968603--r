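#' Plot adjusted median differences
#'
#' Dot-and-interval plot of the covariate-adjusted median differences
#' against the full-time-no-arthritis reference, per group.
#'
#' @param object A [adjusted_median_difference()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plycost_adjdiff <- function(object, ...) {
  est <- dplyr::filter(object$estimates, .data$group != "FT_no_arth")
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = paste("Adjusted median difference vs full-time, no arthritis",
                "(AU$/week, real 2013)"),
      y = NULL, title = object$outcome
    ) +
    ggplot2::theme_minimal()
}

#' Plot national cost components
#'
#' @param object A [national_costs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plycost_national <- function(object, ...) {
  ggplot2::ggplot(object$costs,
                  ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL,
                  y = "AU$ millions per year (real 2013)") +
    ggplot2::theme_minimal()
}

#' Plot a full results bundle
#'
#' National cost components over the projection years.
#'
#' @param object A [run_pipeline()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plycost_results <- function(object, ...) {
  ggplot2::ggplot(object$national,
                  ggplot2::aes(x = .data$year, y = .data$estimate,
                               colour = .data$component)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high,
                   fill = .data$component),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Projection year",
                  y = "AU$ millions per year (real 2013)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
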