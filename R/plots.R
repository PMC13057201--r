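# ggplot2 visualisations of the package's result objects.

#' Plot a permutation null with its observed statistic
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "#2166ac", linewidth = 1) +
    ggplot2::labs(x = object$statistic, y = "shuffles",
                  title = sprintf("observed %.3g, p = %.3g",
                                  object$observed_stat, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot longitudinal category fractions
#'
#' @param object A `dynamics_summary`.
#' @param ... Unused.
#' @return A ggplot of category fractions per status group.
#' @export
autoplot.dynamics_summary <- function(object, ...) {
  ggplot2::ggplot(object$categories,
                  ggplot2::aes(x = .data$category, y = .data$fraction,
                               fill = .data$status)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "fraction of spines", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Survival-fraction and turnover trajectories
#'
#' Line plots of the survival fraction per session and of the turnover
#' ratio per inter-session interval, stratified by status group.
#'
#' @param summary A `dynamics_summary`.
#' @return A ggplot.
#' @export
plot_survival_fraction <- function(summary) {
  ggplot2::ggplot(summary$survival,
                  ggplot2::aes(x = .data$day, y = .data$survival,
                               colour = .data$status)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "day", y = "survival fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_survival_fraction
#' @export
plot_turnover <- function(summary) {
  ggplot2::ggplot(summary$turnover,
                  ggplot2::aes(x = .data$to_day, y = .data$turnover,
                               colour = .data$status)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "turnover ratio", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of spine volume against EPSCaT amplitude
#'
#' @param data Data frame with columns `volume` and `max_dff`.
#' @return A ggplot with a linear trend line.
#' @export
plot_volume_amplitude <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$volume, y = .data$max_dff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#2166ac") +
    ggplot2::labs(x = "spine volume (a.u.)", y = "EPSCaT amplitude (dF/F)") +
    ggplot2::theme_minimal()
}

#' Trial-averaged response against its permutation threshold
#'
#' @param mean_trace Aligned trial-averaged dF/F trace.
#' @param threshold Numeric threshold trace or `permutation_null`.
#' @param window The [trial_window()] used.
#' @param frame_rate Frames per second (for the time axis).
#' @return A ggplot with the stimulation window shaded.
#' @export
plot_mean_response <- function(mean_trace, threshold, window = trial_window(),
                               frame_rate = 30) {
  if (inherits(threshold, "permutation_null")) threshold <- threshold$threshold
  t <- (seq_along(mean_trace) - 1L - window$baseline_frames) / frame_rate
  df <- tibble::tibble(time_s = t, dff = mean_trace, threshold = threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::annotate("rect", xmin = 0,
                      xmax = window$stim_frames / frame_rate,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange") +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), colour = "grey60",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$dff), colour = "#2166ac") +
    ggplot2::labs(x = "time from stimulation onset (s)", y = "dF/F") +
    ggplot2::theme_minimal()
}
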