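# ggplot2 views of streams and results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a labeled stream
#'
#' Acceleration streams are drawn as the three axes plus the magnitude;
#' respiratory streams as the amplitude trace. Label segments are shaded
#' and truth fall times marked.
#'
#' @param object a `labeled_stream`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.labeled_stream <- function(object, ...) {
  if (object$channel == "resp") {
    p <- ggplot2::ggplot(object$stream, ggplot2::aes(x = .data$t,
                                                     y = .data$amplitude)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::labs(x = "time [s]", y = "expansion [a.u.]")
  } else {
    long <- tidyr::pivot_longer(object$stream, c("ax", "ay", "az"),
                                names_to = "axis", values_to = "a")
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$a,
                                            colour = .data$axis)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time [s]", y = expression(acceleration ~ "[m/s"^2 * "]"))
  }
  if (nrow(object$labels) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$labels,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "grey40",
      inherit.aes = FALSE
    )
  }
  if (!is.null(object$truth$falls) && length(object$truth$falls) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$truth$falls,
                                 linetype = "dashed", colour = "red")
  }
  p + ggplot2::ggtitle(object$kind) + ggplot2::theme_minimal()
}

#' Plot detected fall events over their stream
#'
#' @param stream the acceleration stream the events came from.
#' @param events a `fall_events` tibble from [detect_falls()].
#' @return a ggplot object: magnitude trace, impact markers (fall alarms in
#'   red).
#' @export
plot_fall_events <- function(stream, events) {
  stream <- as_accel_stream(stream)
  df <- tibble::tibble(t = stream$t, mag = stream_magnitude(stream))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mag)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = expression("|a| [m/s"^2 * "]")) +
    ggplot2::theme_minimal()
  if (nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(
      data = events,
      ggplot2::aes(xintercept = .data$impact_time,
                   colour = .data$is_fall),
      linetype = "dashed"
    ) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                              `FALSE` = "grey50"),
                                   name = "fall")
  }
  p
}

#' Plot sawtooth cycles over the dominant axis
#'
#' @param stream the acceleration stream.
#' @param cycles the tibble from [parameterize_sawtooth()].
#' @return a ggplot object with cycle peaks and troughs marked.
#' @export
plot_sawtooth <- function(stream, cycles) {
  stream <- as_accel_stream(stream)
  axis <- if (nrow(cycles) > 0) paste0("a", cycles$dominant_axis[1]) else "ax"
  df <- tibble::tibble(t = stream$t, a = stream[[axis]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$a)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]",
                  y = paste0(axis, " [m/s²]")) +
    ggplot2::theme_minimal()
  if (nrow(cycles) > 0) {
    p <- p +
      ggplot2::geom_vline(xintercept = cycles$peak_time, colour = "red",
                          linetype = "dotted") +
      ggplot2::geom_vline(xintercept = cycles$start_time, colour = "grey60",
                          linetype = "dotted")
  }
  p
}

#' Plot a metabolic expenditure report
#'
#' @param object a `met_report` from [estimate_met()].
#' @param ... unused.
#' @return a ggplot object: per-epoch instantaneous expenditure, ascending
#'   epochs highlighted.
#' @export
autoplot.met_report <- function(object, ...) {
  ggplot2::ggplot(object$epochs,
                  ggplot2::aes(x = (.data$t_start + .data$t_end) / 2,
                               y = .data$kcal_min, fill = .data$ascending)) +
    ggplot2::geom_col(width = MET_EPOCH_S * 0.9) +
    ggplot2::labs(x = "time [s]", y = "kcal/min",
                  title = sprintf("cumulative %.2f kcal",
                                  object$cumulative_kcal)) +
    ggplot2::theme_minimal()
}
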