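#' Forest plot of hazard-model coefficients
#'
#' @param object A `hazard_fit`.
#' @param ... Unused.
#' @return A ggplot: coefficient estimates with 95% Wald intervals.
#' @export
autoplot.hazard_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "log hazard ratio", y = NULL,
                  title = "Mortality risk factors") +
    ggplot2::theme_minimal()
}

#' AIC ladder plot
#'
#' @param object A `model_ladder`.
#' @param ... Unused.
#' @return A ggplot of delta-AIC per model specification.
#' @export
autoplot.model_ladder <- function(object, ...) {
  df <- tidy(object)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_aic, y = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 2, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = expression(Delta * AIC), y = NULL) +
    ggplot2::theme_minimal()
}

#' Census-interval bias plot
#'
#' @param object A `cil_fit`.
#' @param ... Unused.
#' @return A ggplot of plot-level proportions against mean census-interval
#'   length with the fitted correction line.
#' @export
autoplot.cil_fit <- function(object, ...) {
  df <- object$fit$model
  names(df) <- c("p_mod", "cil_c")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cil_c + object$cil_center,
                                   y = .data$p_mod)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$beta0 -
                           object$beta1 * object$cil_center,
                         slope = object$beta1) +
    ggplot2::labs(x = "mean census-interval length (yr)",
                  y = paste("proportion", object$mode)) +
    ggplot2::theme_minimal()
}

#' Boxplot of plot-level mortality rates by region
#'
#' @param plot_rates Output of [plot_mortality_rate()].
#' @param comparison Optional [compare_regions()] result whose letters are
#'   annotated above the boxes.
#' @return A ggplot.
#' @export
plot_rate_boxplot <- function(plot_rates, comparison = NULL) {
  p <- ggplot2::ggplot(plot_rates,
                       ggplot2::aes(x = .data$region, y = .data$m_plot,
                                    fill = .data$region)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression("mortality rate (% yr"^-1 * ")")) +
    ggplot2::theme_minimal()
  if (!is.null(comparison)) {
    lab <- comparison$letters
    ymax <- max(plot_rates$m_plot, na.rm = TRUE)
    p <- p + ggplot2::geom_text(
      data = lab, ggplot2::aes(x = .data$region, y = ymax * 1.05,
                               label = .data$letters),
      inherit.aes = FALSE)
  }
  p
}

#' Regional mode-of-death proportions with confidence intervals
#'
#' @param object A `regional_modes` fit.
#' @param ... Unused.
#' @return A ggplot of adjusted proportions and 95% intervals per region.
#' @export
autoplot.regional_modes <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$region, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = NULL,
                  y = paste("adjusted proportion", object$mode)) +
    ggplot2::theme_minimal()
}
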