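#' Plot cohort mean deviation over time with a standard-error ribbon
#'
#' @param summary A [trajectory_summary()] tibble.
#' @return A ggplot object: one panel per axis, line = cohort mean
#'   deviation, ribbon = plus/minus one SEM, coloured by speed condition.
#' @export
plot_trajectory_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$time, y = .data$mean,
    colour = .data$speed, fill = .data$speed
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$axis), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Mean deviation (deg)",
                  colour = "Speed", fill = "Speed") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectory_summary
#' @param object,... `autoplot` arguments.
#' @export
autoplot.trajectory_summary <- function(object, ...) {
  plot_trajectory_summary(object)
}

#' Plot the distribution of conformity scores by axis and speed
#'
#' @param scores A [conformity_scores()] tibble.
#' @return A ggplot object: per-participant scores with the axis/speed
#'   means overlaid.
#' @export
plot_conformity_scores <- function(scores) {
  usable <- scores[!scores$degenerate, ]
  ggplot2::ggplot(usable, ggplot2::aes(x = .data$axis, y = .data$r,
                                       colour = .data$speed)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 4,
                          position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Axis", y = "Conformity r (vs leave-one-out median)",
                  colour = "Speed") +
    ggplot2::theme_minimal()
}

#' Plot the cohort lag histogram
#'
#' @param profile A [cohort_lag_profile()] result.
#' @return A ggplot object; the dashed line marks the cohort median lag
#'   (negative lags = head leads the vehicle).
#' @export
plot_lag_profile <- function(profile) {
  bins <- profile$bins
  ggplot2::ggplot(bins, ggplot2::aes(
    x = (.data$lower_ms + .data$upper_ms) / 2, y = .data$count
  )) +
    ggplot2::geom_col(width = bins$upper_ms[1] - bins$lower_ms[1],
                      fill = "grey40") +
    ggplot2::geom_vline(xintercept = profile$median_ms,
                        linetype = "dashed") +
    ggplot2::labs(x = "Head-to-vehicle lag (ms; negative = head leads)",
                  y = "Participants") +
    ggplot2::theme_minimal()
}
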