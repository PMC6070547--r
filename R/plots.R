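#' Plot a multichannel recording
#'
#' Facets the recording's channels over time.
#'
#' @param object Recording tibble.
#' @param channels Channels to show (default: all non-time columns).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rh_recording <- function(object, channels = NULL, ...) {
  channels <- channels %||% setdiff(names(object), "time")
  long <- tidyr::pivot_longer(as.data.frame(object)[c("time", channels)],
                              -"time", names_to = "channel",
                              values_to = "value")
  long$channel <- factor(long$channel, levels = channels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot a heart-sound segmentation over its signal
#'
#' @param object An `rh_segmentation`.
#' @param signal Optional heart-sound series to draw under the states.
#' @param fs Sampling rate of `signal`, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rh_segmentation <- function(object, signal = NULL, fs = NULL, ...) {
  seg <- as.data.frame(object)
  p <- ggplot2::ggplot()
  if (nrow(seg)) {
    seg$state <- factor(seg$state, levels = HS_STATES)
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$state),
      alpha = 0.3)
  }
  if (!is.null(signal)) {
    stopifnot(!is.null(fs))
    df <- data.frame(time = (seq_along(signal) - 1) / fs, value = signal)
    p <- p + ggplot2::geom_line(data = df,
                                ggplot2::aes(x = .data$time, y = .data$value),
                                linewidth = 0.3)
  }
  p + ggplot2::labs(x = "time (s)", y = NULL, fill = "state")
}

#' Compare IBI series in the style of a beat-timing evaluation
#'
#' @param ibi Measured IBI tibble ([ibi_series()]).
#' @param ref Reference (ECG) IBI tibble.
#' @param band Tolerance band around the reference, s (default 0.1).
#' @return A ggplot object.
#' @export
plot_ibi_comparison <- function(ibi, ref, band = 0.1) {
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = ref,
                         ggplot2::aes(x = .data$time, ymin = .data$ibi - band,
                                      ymax = .data$ibi + band),
                         fill = "grey85") +
    ggplot2::geom_line(data = ref,
                       ggplot2::aes(x = .data$time, y = .data$ibi),
                       colour = "black") +
    ggplot2::geom_line(data = ibi,
                       ggplot2::aes(x = .data$time, y = .data$ibi),
                       colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "IBI (s)")
}
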