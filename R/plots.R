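#' Plot per-group means with SEM and subject spread
#'
#' Standard summary figure for subject-level measurements: one point per
#' group mean with an SEM error bar.
#'
#' @param object a [group_stats()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.synq_group_stats <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.15) +
    ggplot2::labs(x = NULL, y = "group mean ± SEM",
                  subtitle = sprintf("%s, p = %.3g", object$test$name,
                                     object$test$p_value)) +
    ggplot2::theme_classic()
}

#' Plot the per-ROI density distribution
#'
#' @param object a [compute_densities()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.synq_density <- function(object, ...) {
  ggplot2::ggplot(object$per_roi,
                  ggplot2::aes(x = .data$synapse_density_per_mm3)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey80", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$summary$synapse_density_per_mm3,
                        linetype = 2) +
    ggplot2::labs(x = "synapses per mm³ (per ROI)", y = "ROIs") +
    ggplot2::theme_classic()
}

#' Plot a trace excerpt with detected events
#'
#' @param rec a [synq_recording()].
#' @param events optional [detect_events()] tibble; detected onsets are
#'   marked.
#' @param window_s length-2 time window to show, s (default first 5 s).
#' @return A ggplot object.
#' @export
plot_trace <- function(rec, events = NULL, window_s = c(0, 5)) {
  df <- as_tibble(rec)
  df <- df[df$time_s >= window_s[1] & df$time_s <= window_s[2], ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_classic()
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events[events$onset_s >= window_s[1] &
                   events$onset_s <= window_s[2], ]
    p <- p + ggplot2::geom_point(
      data = ev,
      ggplot2::aes(x = .data$onset_s, y = .data$peak_amplitude_pA),
      colour = "seagreen", size = 1)
  }
  p
}
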