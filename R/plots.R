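#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-scenario market impacts
#'
#' Bar chart of the annual consumption decrease (million litres) by
#' scenario, annotated with the average retail price increase.
#'
#' @param object An `ssb_market_impact` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssb_market_impact <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      decrease = -.data$dvolume_total)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario_id, y = .data$decrease)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = scales_percent(.data$price_increase)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      x = "Tax scenario",
      y = "Consumption decrease (million litres/year)",
      title = "SSB consumption response by tax scenario",
      subtitle = "Labels: average retail price increase"
    ) +
    ggplot2::theme_minimal()
}

scales_percent <- function(x) paste0(round(100 * x), "%")

#' Plot a cohort's BMI distribution
#'
#' Histogram of BMI by sex with the WPRO class cut-offs marked.
#'
#' @param object An `ssb_cohort` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssb_cohort <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      bmi = bmi(.data$weight_kg, .data$height_m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bmi)) +
    ggplot2::geom_histogram(binwidth = 0.5, fill = "grey65", colour = "white") +
    ggplot2::geom_vline(xintercept = c(23, 25, 30), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~sex, ncol = 1) +
    ggplot2::labs(x = "BMI (kg/m²)", y = "Adults",
                  title = "Synthetic cohort BMI distribution",
                  subtitle = "Dashed lines: WPRO cut-offs 23 / 25 / 30") +
    ggplot2::theme_minimal()
}

#' Plot prevalence by scenario and class
#'
#' @param object An `ssb_prevalence` tibble from [prevalence_table()].
#' @param stratum Stratum to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssb_prevalence <- function(object, stratum = "both", ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      .data$stratum == !!stratum, .data$class != "below")
  df$scenario_id <- factor(df$scenario_id,
                           levels = unique(object$scenario_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario_id, y = .data$estimate,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Scenario", y = "Weighted prevalence", fill = "BMI class",
                  title = "Overweight and obesity prevalence by scenario") +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo means with uncertainty
#'
#' Dot-and-interval plot (mean plus/minus one Monte Carlo SD) for a chosen
#' output across scenarios and models.
#'
#' @param object An `ssb_mc` object.
#' @param output Which output to display (default avoided diabetes cases).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssb_mc <- function(object, output = "avoided_cases", ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$output == !!output)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario_id, y = .data$mean,
                                   colour = .data$model)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(x = "Scenario", y = output, colour = "PSA model",
                  title = "Monte Carlo means ± 1 SD") +
    ggplot2::theme_minimal()
}
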