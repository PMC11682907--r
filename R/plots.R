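#' Coefficient plot for a fitted mixed model
#'
#' Dot-and-whisker display of the standardized fixed effects with their
#' 95% confidence intervals.
#'
#' @param object A `gazebias_fit`.
#' @param drop_intercept Drop the intercept row (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gazebias_fit
#' @export
autoplot.gazebias_fit <- function(object, drop_intercept = TRUE, ...) {
  fx <- object$fixed_effects
  if (drop_intercept) fx <- filter(fx, .data$term != "(Intercept)")
  ggplot2::ggplot(fx, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::labs(x = "standardized estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bias-score distributions by condition
#'
#' Per-trial emotional bias scores by image-pair condition (and group when
#' available), with the no-bias reference line at 0.5.
#'
#' @param bias A bias tibble from [bias_scores()], optionally with a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_bias_by_condition <- function(bias) {
  p <- ggplot2::ggplot(bias, ggplot2::aes(x = .data$condition,
                                          y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(outlier.alpha = 0.25) +
    ggplot2::labs(x = NULL, y = "emotional bias (dwell proportion)") +
    ggplot2::theme_minimal()
  if ("group" %in% names(bias)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  }
  p
}

#' Age simple slopes across moderator levels
#'
#' The slope of age on the outcome as a function of the ERQ preference
#' level, per condition — the visual unpacking of the
#' age-by-condition-by-preference interaction.
#'
#' @param slopes A tibble from [age_slopes_at_levels()].
#' @return A ggplot object.
#' @export
plot_age_slopes <- function(slopes) {
  has_cond <- "condition" %in% names(slopes)
  aes <- if (has_cond) {
    ggplot2::aes(x = .data$moderator_level, y = .data$slope,
                 colour = .data$condition, group = .data$condition)
  } else {
    ggplot2::aes(x = .data$moderator_level, y = .data$slope, group = 1)
  }
  ggplot2::ggplot(slopes, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::labs(x = "ERQ preference level (reappraisal - suppression)",
                  y = "standardized age slope (95% CI)") +
    ggplot2::theme_minimal()
}
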