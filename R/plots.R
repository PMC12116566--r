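# ggplot2 displays for each result type.

#' Forest plot of a signal scan
#'
#' ROR point estimates with 95% CI per preferred term, log scale, the
#' signal threshold at 1 dashed; signals coloured.
#'
#' @param object A `signal_scan` (or any `signal_result` tibble).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_result <- function(object, ...) {
  df <- dplyr::mutate(object,
                      event = factor(.data$event, levels = rev(.data$event)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$event,
                                   colour = .data$is_signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_lo,
                                         xmax = .data$ror_hi), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#C0392B", `FALSE` = "grey55"),
                                 name = "signal") +
    ggplot2::labs(x = "reporting odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Onset histogram with the fitted Weibull density
#'
#' @param object A `weibull_fit`.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weibull_fit <- function(object, bins = 30, ...) {
  df <- tibble(onset = object$onsets)
  grid <- tibble(t = seq(0.5, max(df$onset), length.out = 200))
  grid$f <- dweibull(grid$t, object$shape, object$scale)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$onset)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "white") +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$t, y = .data$f),
                       colour = "#2C3E50", linewidth = 0.8) +
    ggplot2::labs(
      x = "onset (days)", y = "density",
      subtitle = sprintf("Weibull k = %.2f [%.2f, %.2f], lambda = %.0f d; %s hazard",
                         object$shape, object$shape_lo, object$shape_hi,
                         object$scale, object$hazard_class)
    ) +
    ggplot2::theme_minimal()
}

#' Odds-ratio forest plot of a logistic fit
#'
#' Covariate odds ratios with Wald CIs (intercept omitted), log scale.
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.15) +
    ggplot2::geom_point(size = 2, colour = "#2C3E50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Median onset per drug-PT pair
#'
#' Dot-and-whisker display of the per-pair onset median with interquartile
#' range.
#'
#' @param tto_summary Output of [summarize_tto()].
#' @return A ggplot object.
#' @export
plot_tto_medians <- function(tto_summary) {
  df <- dplyr::mutate(tto_summary,
                      pair = paste(.data$drug, .data$pt, sep = " / "))
  df$pair <- factor(df$pair, levels = rev(df$pair))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_days, y = .data$pair)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$q1_days,
                                         xmax = .data$q3_days), height = 0.2,
                            colour = "grey55") +
    ggplot2::geom_point(size = 2, colour = "#C0392B") +
    ggplot2::labs(x = "time to onset (days, median with IQR)", y = NULL) +
    ggplot2::theme_minimal()
}
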