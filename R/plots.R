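# ggplot2 quick-look figures for the main result types.

#' Plot the capture-aligned coupling series
#'
#' Calls per wingbeat and summed per-wingbeat energy over the last
#' wingbeats before capture (means with +/- 1 sd ribbons): calls per
#' wingbeat rises into the buzz while the summed energy falls.
#'
#' @param object A `capture_alignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.capture_alignment <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  long <- dplyr::bind_rows(
    dplyr::transmute(d, wb_index = .data$wb_index, metric = "calls per wingbeat",
                     mean = .data$mean_calls_per_wb,
                     lo = .data$mean_calls_per_wb - .data$sd_calls_per_wb,
                     hi = .data$mean_calls_per_wb + .data$sd_calls_per_wb),
    dplyr::transmute(d, wb_index = .data$wb_index,
                     metric = "summed EFD (dB re 20 uPa2s)",
                     mean = .data$mean_summed_efd_db,
                     lo = .data$mean_summed_efd_db - .data$sd_summed_efd_db,
                     hi = .data$mean_summed_efd_db + .data$sd_summed_efd_db)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$wb_index, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "wingbeat index before capture", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot phase histograms by interval class
#'
#' @param object A `phase_histogram`.
#' @param normalized Plot normalised curves (default) or raw counts.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_histogram <- function(object, normalized = TRUE, ...) {
  d <- object$histogram
  y <- if (normalized) "normalized" else "count"
  ggplot2::ggplot(d, ggplot2::aes(.data$phase_mid_deg, .data[[y]],
                                  colour = .data$interval_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 180, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, 90), limits = c(0, 360)) +
    ggplot2::labs(x = "wingbeat phase (deg; upstroke 0-180)", y = y,
                  colour = "interval class") +
    ggplot2::theme_minimal()
}

#' Plot source level versus call interval
#'
#' @param object A `level_interval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.level_interval <- function(object, ...) {
  d <- object$bins[!is.na(object$bins$median_sl_efd_db), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(sqrt(.data$interval_lo_ms * .data$interval_hi_ms),
                                       .data$median_sl_efd_db)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "call interval (ms)",
                  y = "source level (dB re 20 uPa2s EFD)") +
    ggplot2::theme_minimal()
  if (!is.null(object$transition_band_ms)) {
    p <- p + ggplot2::annotate("rect", xmin = object$transition_band_ms[1],
                               xmax = object$transition_band_ms[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}

#' Plot the stroke-frequency spectrogram peak track
#'
#' @param object A `wb_spectrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wb_spectrogram <- function(object, ...) {
  ggplot2::ggplot(object$track, ggplot2::aes(.data$time_s, .data$peak_hz,
                                             colour = .data$reliable)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "time (s)", y = "stroke frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
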