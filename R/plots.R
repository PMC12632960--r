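#' Plot predicted versus chronological age
#'
#' Scatter of predictions against true ages with the identity line, one
#' panel-free overview across repeats.
#'
#' @param object a `prediction_set`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot prediction_set
#' @export
autoplot.prediction_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$age, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "Chronological age (years)", y = "Predicted age (years)") +
    ggplot2::theme_minimal()
}

#' Plot the brain-age gap against chronological age
#'
#' Visualizes the age bias: a trend in the gap across age means prediction
#' errors are systematically age-dependent.
#'
#' @param object a `brain_age_gap` tibble (see [brain_age_delta()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot brain_age_gap
#' @export
autoplot.brain_age_gap <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$age, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    ggplot2::labs(x = "Chronological age (years)", y = "Brain-age gap (years)") +
    ggplot2::theme_minimal()
}

#' Plot metric summaries of an experiment
#'
#' One point per feature-block configuration and metric, with SD error bars
#' (across repeats).
#'
#' @param object an `experiment_result`.
#' @param metrics which metrics to show.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot experiment_result
#' @export
autoplot.experiment_result <- function(object, metrics = c("mae", "r2"), ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(cols = dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value")
  sd_long <- as_tibble(object) |>
    tidyr::pivot_longer(cols = dplyr::all_of(paste0(metrics, "_sd")),
                        names_to = "metric", values_to = "sd") |>
    dplyr::mutate(metric = sub("_sd$", "", .data$metric))
  long$sd <- sd_long$sd
  ggplot2::ggplot(long, ggplot2::aes(x = .data$block, y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$sd,
                                          ymax = .data$value + .data$sd)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Feature block", y = NULL) +
    ggplot2::theme_minimal()
}
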