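#' Cohort trend plot (grey per-subject lines, red cohort mean)
#'
#' @param trend Output of [long_term_trend()] or [cohort_long_term()].
#' @param feature Axis label for the feature plotted.
#' @return A ggplot object.
#' @export
plot_long_term_trend <- function(trend, feature = "rEEG (µV)") {
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = trend$subjects,
      ggplot2::aes(x = .data$time / 60, y = .data$value,
                   group = .data$subject_id),
      colour = "grey60", linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(
      data = trend$cohort,
      ggplot2::aes(x = .data$time / 60, y = .data$mean),
      colour = "red", linewidth = 0.9, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from drug administration (min)", y = feature) +
    ggplot2::theme_minimal()
}

#' Delta-versus-baseline scatter plot
#'
#' One point per subject: the pre-drug baseline median on the x axis and
#' the post-minus-baseline delta on the y axis. A negative trend means the
#' drug suppresses activity more in subjects who started higher.
#'
#' @param scatter The `scatter` table from [run_cohort_analyses()]
#'   (optionally filtered to one comparison).
#' @return A ggplot object.
#' @export
plot_delta_scatter <- function(scatter) {
  ggplot2::ggplot(scatter,
                  ggplot2::aes(x = .data$baseline, y = .data$delta)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~ feature + comparison, scales = "free") +
    ggplot2::labs(x = "Baseline median", y = "Delta (post - baseline)") +
    ggplot2::theme_minimal()
}
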