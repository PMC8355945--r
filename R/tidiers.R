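# broom-style tidiers for the pipeline's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a capture-aligned series
#'
#' @param x A `capture_alignment` from [align_to_capture()].
#' @param ... Unused.
#' @return The per-index tibble (means and sds by wingbeat index).
#' @export
tidy.capture_alignment <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a phase histogram
#'
#' @param x A `phase_histogram` from [phase_histogram()].
#' @param ... Unused.
#' @return The long histogram tibble.
#' @export
tidy.phase_histogram <- function(x, ...) x$histogram

#' Tidy a level-versus-interval summary
#'
#' @param x A `level_interval` from [level_vs_interval()].
#' @param ... Unused.
#' @return The binned summary tibble.
#' @export
tidy.level_interval <- function(x, ...) x$bins

#' One-row summary of a tag analysis
#'
#' @param x A `tag_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble: counts, buzz-call fraction, median call phase,
#'   median wingbeat frequency, median RMS source level of wingbeat-locked
#'   calls.
#' @export
glance.tag_analysis <- function(x, ...) {
  slow <- c("one_per_wb", "one_per_2wb", "one_per_3wb")
  buzz <- c("buzzI", "buzzII")
  tibble::tibble(
    n_calls = nrow(x$calls),
    n_cycles = nrow(x$cycles),
    n_captures = nrow(x$events),
    buzz_call_fraction = mean(x$calls$interval_class %in% buzz),
    median_phase_deg = circ_median(x$calls$phase_deg),
    median_wb_freq_hz = median(x$cycles$freq_hz),
    median_slow_sl_rms_db = median(
      x$calls$sl_rms_db[x$calls$interval_class %in% slow], na.rm = TRUE)
  )
}
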