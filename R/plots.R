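# Diagnostic plots: a trace with its segmentation, and an arousal clock.

#' Plot a skin-temperature trace with its segmentation
#'
#' @param trace A decoded trace.
#' @param segmentation Optional [segment_trace()] result; detected bouts are
#'   shaded and arousals marked.
#' @param threshold Optional onset threshold drawn as a dashed line
#'   (defaults to the segmentation's threshold when available).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, segmentation = NULL, threshold = NULL) {
  assert_cols(trace, c("timestamp", "tsk_C"), "trace")
  threshold <- threshold %||% segmentation$params$threshold
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$timestamp, .data$tsk_C)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Skin temperature (°C)")
  if (!is.null(segmentation) && nrow(segmentation$bouts) > 0) {
    b <- filter(segmentation$bouts, .data$bat_id == trace$bat_id[1])
    p <- p +
      ggplot2::geom_rect(
        data = b,
        ggplot2::aes(xmin = .data$onset, xmax = .data$end,
                     fill = .data$censored),
        ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "grey50"),
                                 guide = "none")
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' @export
autoplot.torpor_segmentation <- function(object, trace, ...) {
  plot_trace(trace, segmentation = object)
}

#' Circular histogram of arousal times relative to sunset
#'
#' @param arousals Arousal table with `rel_sunset_h` (and optionally `site`
#'   for faceting).
#' @param binwidth_h Bin width in hours (default 1).
#' @return A ggplot object on polar coordinates; sunset at the top.
#' @export
plot_arousal_clock <- function(arousals, binwidth_h = 1) {
  assert_cols(arousals, "rel_sunset_h", "arousals")
  df <- filter(arousals, is.finite(.data$rel_sunset_h)) %>%
    mutate(clock_h = .data$rel_sunset_h %% 24)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$clock_h)) +
    ggplot2::geom_histogram(binwidth = binwidth_h, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 21, by = 3),
                                labels = function(x) sprintf("%+d h", x)) +
    ggplot2::labs(x = "Time relative to sunset", y = NULL)
  if ("site" %in% names(df)) p <- p + ggplot2::facet_wrap(~site)
  p
}
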