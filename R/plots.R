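# autoplot() methods: quick-look figures for each result type

#' Plot a displacement trace
#'
#' @param object A `displacement_trace` from [track_stack()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.displacement_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$disp_um)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(data = dplyr::filter(object, .data$low_confidence),
                        colour = "red", size = 1) +
    ggplot2::labs(x = "time (s)", y = "pillar displacement (µm)",
                  title = sprintf("POC tracking (%s)", attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' Plot a force trace
#'
#' @param object A `force_trace` from [displacement_to_force()].
#' @param metrics Optional [beat_metrics()] whose per-beat peaks are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.force_trace <- function(object, metrics = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_s, y = .data$force_n * 1e6)) +
    ggplot2::geom_line(colour = "#31a354") +
    ggplot2::labs(x = "time (s)", y = "force (µN)",
                  title = "Contractile force (cantilever model)") +
    ggplot2::theme_minimal()
  if (!is.null(metrics) && metrics$detected) {
    p <- p + ggplot2::geom_point(
      data = metrics$beats,
      ggplot2::aes(x = .data$time_s, y = .data$peak_force_n * 1e6),
      colour = "#e6550d", size = 2)
  }
  p
}

#' Box-and-whisker plot of a two-group comparison
#'
#' Boxes span the 25th-75th percentiles, the horizontal line is the median,
#' whiskers reach the minimum and maximum, and individual samples are
#' overlaid.
#'
#' @param object A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q25,
                                        ymax = .data$q75),
                           fill = "grey85", width = 0.5) +
    ggplot2::geom_jitter(data = object$data,
                         ggplot2::aes(x = .data$group, y = .data$value),
                         width = 0.08, colour = "#2c7fb8", alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "value",
                  subtitle = sprintf("%s t test: p = %.3g %s", object$method,
                                     object$p_value,
                                     significance_stars(object$p_value))) +
    ggplot2::theme_minimal()
}
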