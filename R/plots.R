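#' Plot a simulated trajectory
#'
#' Central concentrations of the original and modified forms over time.
#'
#' @param object A `pk_trajectory` from [simulate_attribute()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_trajectory <- function(object, ...) {
  d <- object %>%
    select("time_days", "C0", "Cmod") %>%
    tidyr::pivot_longer(c("C0", "Cmod"), names_to = "form",
                        values_to = "concentration") %>%
    mutate(form = dplyr::recode(.data$form, C0 = "original",
                                Cmod = "modified"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_days, .data$concentration,
                                  colour = .data$form)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (days)", y = "Central concentration",
                  colour = "Form") +
    ggplot2::theme_minimal()
}

#' Plot an exposure sweep
#'
#' Relative AUC against the initial attribute level.
#'
#' @param object An `exposure_summary` from [relative_auc_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exposure_summary <- function(object, ...) {
  gg <- ggplot2::ggplot(object,
                        ggplot2::aes(.data$initial_level_pct,
                                     .data$relative_auc_pct))
  if ("attribute" %in% names(object))
    gg <- gg + ggplot2::aes(colour = .data$attribute)
  gg +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Initial level (%)", y = "Relative AUC (%)") +
    ggplot2::theme_minimal()
}

#' Plot attribute time courses
#'
#' Relative attribute levels (percent) against collection time, one line
#' per subject, faceted by attribute.
#'
#' @param series Tibble (`attribute`, `subject`, `time_days`, `fraction`)
#'   as returned by [relative_percent()] / [quantify_study()].
#' @return A ggplot.
#' @export
plot_attribute_series <- function(series) {
  ggplot2::ggplot(
    series %>% filter(!is.na(.data$fraction)),
    ggplot2::aes(.data$time_days, 100 * .data$fraction,
                 colour = .data$subject)
  ) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~attribute, scales = "free_y") +
    ggplot2::labs(x = "Time (days)", y = "Relative level (%)",
                  colour = "Subject") +
    ggplot2::theme_minimal()
}

#' Plot concentration time courses
#'
#' Total drug concentration per subject on a log scale.
#'
#' @param series Tibble (`subject`, `time_days`, `concentration`).
#' @return A ggplot.
#' @export
plot_concentration_series <- function(series) {
  ggplot2::ggplot(
    series %>% filter(is.finite(.data$concentration),
                      .data$concentration > 0),
    ggplot2::aes(.data$time_days, .data$concentration,
                 colour = .data$subject)
  ) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (days)", y = "Concentration (ug/mL)",
                  colour = "Subject") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
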