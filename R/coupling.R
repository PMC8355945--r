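# Vocal-locomotor coupling metrics: per-call wingbeat phase, per-wingbeat
# call counts and summed energy, capture-aligned series over the last ten
# wingbeats, phase histograms by interval class, and the source-level vs
# call-interval summary.

#' Assign a wingbeat phase to each call
#'
#' Samples the wingbeat phase series at each call's peak time (nearest
#' accelerometer sample). Calls during masked, non-flight spans get `NA`.
#' Upstroke is 0-180 deg.
#'
#' @param calls Call table with `t_peak`.
#' @param phase Phase series from [compute_phase()].
#' @return `calls` with a `phase_deg` column.
#' @export
assign_phase <- function(calls, phase) {
  fs <- infer_fs(phase$time_s)
  idx <- round((calls$t_peak - phase$time_s[1]) * fs) + 1
  idx[idx < 1 | idx > nrow(phase)] <- NA
  dplyr::mutate(tibble::as_tibble(calls), phase_deg = phase$phase_deg[idx])
}

#' Per-wingbeat coupling metrics
#'
#' Assigns each call to the unique wingbeat cycle containing its peak time
#' and summarises per cycle: number of calls, call rate, and the summed
#' energy flux density of the member calls' source levels (energy-domain
#' sum, `10 log10(sum 10^(SL/10))`). Cycles without calls carry `NA`
#' summed EFD (never `-Inf`). Calls outside every cycle are returned in the
#' `uncycled` attribute.
#'
#' @param calls Call table with `t_peak` and `sl_efd_db`.
#' @param cycles Wingbeat cycles from [detect_wingbeats()].
#' @return Tibble: `cycle`, `t_start`, `t_end`, `duration_s`, `freq_hz`,
#'   `n_calls`, `call_rate_hz`, `summed_efd_db`; attribute `uncycled` holds
#'   the call indices assigned to no cycle.
#' @export
per_wingbeat_metrics <- function(calls, cycles) {
  stopifnot(!is.unsorted(calls$t_peak))
  k <- findInterval(calls$t_peak, cycles$t_start)
  in_cycle <- k >= 1 & k <= nrow(cycles) & calls$t_peak < cycles$t_end[pmax(k, 1)]
  k[!in_cycle] <- NA
  energy <- db_to_energy(calls$sl_efd_db)
  n_calls <- tabulate(k[!is.na(k)], nbins = nrow(cycles))
  esum <- rep(0, nrow(cycles))
  ok <- !is.na(k) & !is.na(energy)
  if (any(ok)) {
    agg <- tapply(energy[ok], k[ok], sum)
    esum[as.integer(names(agg))] <- agg
  }
  out <- tibble::tibble(
    cycle = cycles$cycle,
    t_start = cycles$t_start,
    t_end = cycles$t_end,
    duration_s = cycles$duration_s,
    freq_hz = cycles$freq_hz,
    n_calls = n_calls,
    call_rate_hz = n_calls / cycles$duration_s,
    summed_efd_db = ifelse(n_calls > 0, energy_to_db(esum), NA_real_)
  )
  attr(out, "uncycled") <- which(!in_cycle)
  out
}

#' Capture-aligned series over the last wingbeats before capture
#'
#' For each capture event, indexes whole wingbeat cycles backwards from the
#' cycle containing the capture time (index -1) and averages call rate,
#' wingbeat frequency, calls per wingbeat and summed EFD across events at
#' each index. Events with fewer preceding cycles contribute missing
#' leading values. Summed EFD is averaged in the energy domain.
#'
#' @param events Capture events with `t_capture`.
#' @param wb_metrics Per-wingbeat metrics from [per_wingbeat_metrics()].
#' @param n_cycles Number of pre-capture cycles (default 10).
#' @return Object of class `capture_alignment`: tibble `wb_index`
#'   (-n_cycles..-1), `n_events`, and mean/sd columns for `calls_per_wb`,
#'   `call_rate_hz`, `wb_freq_hz`, `summed_efd_db`.
#' @export
align_to_capture <- function(events, wb_metrics, n_cycles = 10) {
  if (!nrow(events)) abort("at least one capture event is required")
  per_event <- purrr::map_dfr(seq_len(nrow(events)), function(e) {
    tc <- events$t_capture[e]
    i_cap <- which(wb_metrics$t_start <= tc & wb_metrics$t_end > tc)
    if (!length(i_cap)) return(NULL)
    i_cap <- i_cap[1]
    idx <- (i_cap - n_cycles + 1):i_cap
    sel <- idx >= 1
    tibble::tibble(
      event = e,
      wb_index = (-n_cycles:-1)[sel],
      calls_per_wb = wb_metrics$n_calls[idx[sel]],
      call_rate_hz = wb_metrics$call_rate_hz[idx[sel]],
      wb_freq_hz = wb_metrics$freq_hz[idx[sel]],
      summed_efd_db = wb_metrics$summed_efd_db[idx[sel]]
    )
  })
  if (!nrow(per_event)) {
    # no event's capture time falls inside a closed cycle (e.g. the record
    # ends mid-buzz): return an all-NA frame of the right shape
    per_event <- tibble::tibble(event = integer(0), wb_index = integer(0),
                                calls_per_wb = numeric(0),
                                call_rate_hz = numeric(0),
                                wb_freq_hz = numeric(0),
                                summed_efd_db = numeric(0))
  }
  agg <- per_event |>
    dplyr::group_by(.data$wb_index) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      mean_calls_per_wb = mean(.data$calls_per_wb),
      sd_calls_per_wb = sd(.data$calls_per_wb),
      mean_call_rate_hz = mean(.data$call_rate_hz),
      sd_call_rate_hz = sd(.data$call_rate_hz),
      mean_wb_freq_hz = mean(.data$wb_freq_hz),
      sd_wb_freq_hz = sd(.data$wb_freq_hz),
      mean_summed_efd_db = energy_to_db(mean(db_to_energy(.data$summed_efd_db),
                                             na.rm = TRUE)),
      sd_summed_efd_db = sd(.data$summed_efd_db, na.rm = TRUE),
      .groups = "drop"
    )
  structure(agg, class = c("capture_alignment", class(agg)),
            per_event = per_event)
}

#' Phase histograms by call-interval class
#'
#' Circular histograms of call phase per interval class, in counts and
#' normalised (peak = 1) form, with circular median and quartiles per class.
#' Classes with fewer than `min_calls` calls keep their counts but have the
#' normalised curve suppressed.
#'
#' @param calls Classified call table with `phase_deg` and `interval_class`.
#' @param bin_deg Histogram bin width, degrees.
#' @param min_calls Minimum class size for a normalised curve.
#' @return Object of class `phase_histogram`: list with `histogram`
#'   (tibble: `interval_class`, `phase_mid_deg`, `count`, `normalized`) and
#'   `summary` (tibble: `interval_class`, `n`, `q25`, `median`, `q75`).
#' @export
phase_histogram <- function(calls, bin_deg = 10, min_calls = 10) {
  cc <- calls[!is.na(calls$phase_deg), ]
  breaks <- seq(0, 360, by = bin_deg)
  mids <- breaks[-1] - bin_deg / 2
  hist_tb <- cc |>
    dplyr::group_by(.data$interval_class) |>
    dplyr::group_modify(function(d, key) {
      cnt <- tabulate(pmin(length(mids), floor(d$phase_deg / bin_deg) + 1L),
                      nbins = length(mids))
      norm <- if (nrow(d) >= min_calls) cnt / max(cnt) else rep(NA_real_, length(cnt))
      tibble::tibble(phase_mid_deg = mids, count = cnt, normalized = norm)
    }) |>
    dplyr::ungroup()
  summ <- cc |>
    dplyr::group_by(.data$interval_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      q25 = circ_quartiles(.data$phase_deg)[["q25"]],
      median = circ_median(.data$phase_deg),
      q75 = circ_quartiles(.data$phase_deg)[["q75"]],
      .groups = "drop"
    )
  structure(list(histogram = hist_tb, summary = summ),
            class = "phase_histogram")
}

#' Source level versus call interval
#'
#' Summarises source EFD levels per (roughly log-spaced) call-interval bin
#' and flags the transition band in which levels drop: the gap between the
#' last quiet bin and the first loud bin at the largest median jump (about
#' 60-70 ms in foraging bats, where the emission switches from one-two loud
#' calls per wingbeat to many faint ones).
#'
#' @param calls Call table with `interval_prev_ms` and `sl_efd_db`.
#' @param breaks_ms Interval bin edges, ms.
#' @return Object of class `level_interval`: list with `bins` (tibble:
#'   `interval_lo_ms`, `interval_hi_ms`, `n`, `median_sl_efd_db`, `q25`,
#'   `q75`) and `transition_band_ms` (`c(lo, hi)` or `NULL`).
#' @export
level_vs_interval <- function(calls,
                              breaks_ms = c(4, 7, 14, 25, 40, 50, 60, 70, 85,
                                            100, 150, 200, 300, 400, 600, 1000)) {
  if (!nrow(calls)) abort("at least one call is required")
  cc <- calls[!is.na(calls$interval_prev_ms) & !is.na(calls$sl_efd_db), ]
  b <- findInterval(cc$interval_prev_ms, breaks_ms)
  keep <- b >= 1 & b < length(breaks_ms)
  cc <- cc[keep, ]; b <- b[keep]
  bins <- tibble::tibble(
    bin = seq_len(length(breaks_ms) - 1),
    interval_lo_ms = breaks_ms[-length(breaks_ms)],
    interval_hi_ms = breaks_ms[-1]
  )
  summ <- tibble::tibble(bin = b, sl = cc$sl_efd_db) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     median_sl_efd_db = median(.data$sl),
                     q25 = quantile(.data$sl, 0.25, names = FALSE),
                     q75 = quantile(.data$sl, 0.75, names = FALSE),
                     .groups = "drop")
  bins <- dplyr::left_join(bins, summ, by = "bin")
  occ <- bins[!is.na(bins$median_sl_efd_db), ]
  band <- NULL
  if (nrow(occ) >= 2) {
    jumps <- diff(occ$median_sl_efd_db)  # ascending interval: quiet -> loud
    j <- which.max(jumps)
    if (jumps[j] > 3) {
      band <- c(occ$interval_hi_ms[j], occ$interval_lo_ms[j + 1])
    }
  }
  structure(list(bins = dplyr::select(bins, -"bin"),
                 transition_band_ms = band),
            class = "level_interval")
}

#' Distribution of calls per second
#'
#' Histogram of the per-second call count over the analysed span (the
#' calls-per-second distribution contrasting slow wingbeat-locked sampling
#' with buzz rates above 160 calls/s).
#'
#' @param calls Call table with `t_peak`.
#' @param span Optional `c(t0, t1)`; defaults to the call extent.
#' @return Tibble `calls_per_s`, `n_seconds`.
#' @export
call_rate_histogram <- function(calls, span = NULL) {
  span <- span %||% range(calls$t_peak)
  sec <- floor(calls$t_peak - span[1])
  sec <- sec[sec >= 0 & calls$t_peak <= span[2]]
  n_sec <- max(1, ceiling(span[2] - span[1]))
  per_sec <- tabulate(sec + 1L, nbins = n_sec)
  tibble::as_tibble(as.data.frame(table(calls_per_s = per_sec),
                                  stringsAsFactors = FALSE)) |>
    dplyr::mutate(calls_per_s = as.integer(.data$calls_per_s)) |>
    dplyr::rename(n_seconds = "Freq")
}
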