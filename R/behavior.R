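# Rule-based behavioural segmentation of a call/motion record: call-interval
# classes, buzz-terminated capture events, aerial vs landing discrimination,
# commuting-flight windows and an automated approach-onset rule.

INTERVAL_CLASSES <- c("buzzII", "buzzI", "multi_per_wb", "one_per_wb",
                      "one_per_2wb", "one_per_3wb", "unclassified")

#' Call-interval class presets
#'
#' Default bins follow the behavioural definitions: buzz II 4-7 ms, buzz I
#' 7-14 ms, then 14-100 ms (more than one call per wingbeat), 100-200 ms
#' (one per wingbeat), 200-400 ms (one per two wingbeats), 400-600 ms (one
#' per three). The `"fig4"` preset instead uses 5-7 ms buzz II and 8-14 ms
#' buzz I bins. All bins are half-open `[lo, hi)`.
#'
#' @param preset `"definitions"` (default) or `"fig4"`.
#' @return Named list of numeric `c(lo, hi)` bins in ms.
#' @export
interval_bins <- function(preset = c("definitions", "fig4")) {
  preset <- match.arg(preset)
  if (preset == "definitions") {
    list(buzzII = c(4, 7), buzzI = c(7, 14), multi_per_wb = c(14, 100),
         one_per_wb = c(100, 200), one_per_2wb = c(200, 400),
         one_per_3wb = c(400, 600))
  } else {
    list(buzzII = c(5, 7), buzzI = c(8, 14), multi_per_wb = c(14, 100),
         one_per_wb = c(100, 200), one_per_2wb = c(200, 400),
         one_per_3wb = c(400, 600))
  }
}

#' Classify calls by the interval to the previous call
#'
#' @param calls Call table with `interval_prev_ms` (see [analyze_audio()]).
#' @param bins Bin list from [interval_bins()] (half-open, ms).
#' @return `calls` with an `interval_class` factor column added.
#' @export
#' @examples
#' calls <- tibble::tibble(interval_prev_ms = c(NA, 5, 10, 150, 300))
#' classify_intervals(calls)$interval_class
classify_intervals <- function(calls, bins = interval_bins()) {
  iv <- calls$interval_prev_ms
  if (any(iv < 0, na.rm = TRUE)) abort("negative call interval in record")
  cls <- rep("unclassified", length(iv))
  for (nm in names(bins)) {
    b <- bins[[nm]]
    cls[!is.na(iv) & iv >= b[1] & iv < b[2]] <- nm
  }
  dplyr::mutate(tibble::as_tibble(calls),
                interval_class = factor(cls, levels = INTERVAL_CLASSES))
}

#' Detect buzzes and define capture events
#'
#' A buzz is a maximal run of at least `min_run` consecutive calls whose
#' preceding interval is under `buzz_max_ms` (14 ms); the call opening the
#' run is included as a member. The terminal sub-run with intervals under
#' 7 ms is buzz II, and the capture time is the emission time of the last
#' buzz call. Runs separated by more than `max_gap_ms` are distinct buzzes.
#' By default a run of buzz I calls with no buzz II tail still counts as a
#' capture attempt; set `require_buzzII = TRUE` to drop such runs.
#'
#' @param calls Call table with `t_peak` and `interval_prev_ms`.
#' @param min_run Minimum number of sub-14 ms intervals in a buzz.
#' @param buzz_max_ms,buzzII_max_ms Upper interval bounds for buzz and
#'   buzz II calls, ms.
#' @param max_gap_ms Gap that separates distinct buzzes, ms.
#' @param require_buzzII Drop buzz-I-only runs when `TRUE`.
#' @return Tibble of capture events: `event`, `t_buzz_start`,
#'   `t_buzzII_start` (NA when no buzz II tail), `t_capture`, `n_calls`,
#'   `first_call`, `last_call`.
#' @export
detect_buzzes <- function(calls, min_run = 5, buzz_max_ms = 14,
                          buzzII_max_ms = 7, max_gap_ms = 100,
                          require_buzzII = FALSE) {
  empty <- tibble::tibble(event = integer(0), t_buzz_start = numeric(0),
                          t_buzzII_start = numeric(0), t_capture = numeric(0),
                          n_calls = integer(0), first_call = integer(0),
                          last_call = integer(0))
  if (!nrow(calls)) return(empty)
  iv <- calls$interval_prev_ms
  fast <- !is.na(iv) & iv < buzz_max_ms
  if (!any(fast)) return(empty)
  idx <- which(fast)
  grp <- cumsum(c(TRUE, diff(idx) != 1))
  runs <- split(idx, grp)
  # merge runs whose separating pause is at most max_gap_ms (buzz I pauses
  # should not split a capture attempt)
  if (length(runs) > 1) {
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      prev <- merged[[length(merged)]]
      gap_ms <- (calls$t_peak[r[1]] - calls$t_peak[prev[length(prev)]]) * 1000
      if (gap_ms <= max_gap_ms) {
        merged[[length(merged)]] <- c(prev, r)
      } else {
        merged[[length(merged) + 1]] <- r
      }
    }
    runs <- merged
  }
  ev <- purrr::map_dfr(runs, function(run) {
    if (length(run) < min_run) return(NULL)
    members <- c(run[1] - 1L, run)  # the opening call starts the buzz
    # terminal sub-run of buzz II intervals
    b2 <- !is.na(iv[run]) & iv[run] < buzzII_max_ms
    r <- rle(rev(b2))
    n_tail <- if (r$values[1]) r$lengths[1] else 0L
    t_b2 <- if (n_tail > 0) calls$t_peak[run[length(run) - n_tail + 1]] else NA_real_
    tibble::tibble(
      t_buzz_start = calls$t_peak[members[1]],
      t_buzzII_start = t_b2,
      t_capture = calls$t_peak[members[length(members)]],
      n_calls = length(members),
      first_call = members[1],
      last_call = members[length(members)]
    )
  })
  if (!nrow(ev)) return(empty)
  if (require_buzzII) ev <- ev[!is.na(ev$t_buzzII_start), ]
  if (!nrow(ev)) return(empty)
  dplyr::mutate(dplyr::arrange(ev, .data$t_buzz_start),
                event = dplyr::row_number(), .before = 1)
}

#' Flag aerial captures
#'
#' A buzz is aerial when vigorous wingbeats (cycles with peak-to-trough
#' amplitude above `min_amp_ms2`) cover at least `min_coverage` of the
#' window from half a second before the buzz start to the capture; landing
#' or perched buzzes fail this. Events without accelerometer overlap get
#' `NA`.
#'
#' @param events Capture events from [detect_buzzes()].
#' @param cycles Wingbeat cycles from [detect_wingbeats()].
#' @param min_amp_ms2 Amplitude threshold for a "flying" cycle, m/s^2.
#' @param min_coverage Required time-coverage fraction.
#' @param lead_s Window lead before the buzz start, s.
#' @param accel_span Optional `c(t0, t1)` span of the accelerometer record;
#'   events not covered by it get `NA` (unknown).
#' @return `events` with an `is_aerial` logical column.
#' @export
flag_aerial <- function(events, cycles, min_amp_ms2 = 2, min_coverage = 0.8,
                        lead_s = 0.5, accel_span = NULL) {
  flying <- cycles[cycles$amp_ms2 >= min_amp_ms2, ]
  events$is_aerial <- purrr::map2_lgl(
    events$t_buzz_start, events$t_capture,
    function(t0, t1) {
      w0 <- t0 - lead_s
      if (!is.null(accel_span) &&
          (w0 < accel_span[1] - 0.5 || t1 > accel_span[2] + 0.5)) {
        return(NA)  # no accelerometer overlap: unknown
      }
      if (!nrow(flying)) return(FALSE)
      cov <- sum(pmax(0, pmin(flying$t_end, t1) - pmax(flying$t_start, w0)))
      cov / (t1 - w0) >= min_coverage
    }
  )
  events
}

#' Detect commuting-flight windows
#'
#' Commuting flight is a maximal window of at least `min_duration_s`
#' (default 100 s) containing no buzz events, in which at least
#' `min_slow_fraction` of the calls belong to the slow, wingbeat-locked
#' interval classes (one call per 1, 2 or 3 wingbeats) and the median
#' wingbeat frequency lies in `freq_range` (about 7 Hz).
#'
#' @param calls Classified call table (see [classify_intervals()]).
#' @param cycles Wingbeat cycles.
#' @param events Capture events (possibly empty).
#' @param min_duration_s Minimum window length, s.
#' @param min_slow_fraction Required fraction of wingbeat-locked calls.
#' @param freq_range Admissible median wingbeat frequency, Hz.
#' @param span Optional `c(t0, t1)` analysed span; defaults to the call/cycle
#'   extent.
#' @return Tibble of segments: `state` (`"commute"`), `t_start`, `t_end`.
#' @export
detect_commute <- function(calls, cycles, events, min_duration_s = 100,
                           min_slow_fraction = 0.9, freq_range = c(6, 8),
                           span = NULL) {
  span <- span %||% range(c(calls$t_peak, cycles$t_start, cycles$t_end))
  # candidate windows: the gaps between buzz events
  edges <- sort(c(span[1], rbind(events$t_buzz_start, events$t_capture), span[2]))
  starts <- edges[seq(1, length(edges) - 1, by = 2)]
  ends <- edges[seq(2, length(edges), by = 2)]
  slow <- c("one_per_wb", "one_per_2wb", "one_per_3wb")
  out <- purrr::map2_dfr(starts, ends, function(t0, t1) {
    if (t1 - t0 < min_duration_s) return(NULL)
    cc <- calls[calls$t_peak >= t0 & calls$t_peak < t1, ]
    cy <- cycles[cycles$t_start >= t0 & cycles$t_end <= t1, ]
    if (!nrow(cc) || !nrow(cy)) return(NULL)
    classified <- cc$interval_class != "unclassified"
    if (mean(cc$interval_class[classified] %in% slow) < min_slow_fraction)
      return(NULL)
    mf <- median(cy$freq_hz)
    if (mf < freq_range[1] || mf > freq_range[2]) return(NULL)
    tibble::tibble(state = "commute", t_start = t0, t_end = t1)
  })
  out
}

#' Automated approach-onset rule
#'
#' The approach onset is the start of the earliest wingbeat cycle, within
#' `lookback_s` before the capture, from which at least two calls per
#' wingbeat are sustained for at least `min_consecutive` consecutive cycles
#' through to the buzz. If the criterion is never met the onset degenerates
#' to the buzz start (a fast attack with no approach phase). Accuracy is
#' one wingbeat cycle by construction.
#'
#' @param events Capture events.
#' @param wb_metrics Per-wingbeat metrics from [per_wingbeat_metrics()]
#'   joined with cycle times (`t_start`, `t_end`, `n_calls`).
#' @param lookback_s Search window before capture, s.
#' @param min_consecutive Minimum consecutive qualifying cycles.
#' @return `events` with a `t_approach_onset` column.
#' @export
detect_approach_onset <- function(events, wb_metrics, lookback_s = 5,
                                  min_consecutive = 2) {
  events$t_approach_onset <- purrr::map2_dbl(
    events$t_capture, events$t_buzz_start,
    function(tc, tb) {
      w <- wb_metrics[wb_metrics$t_end > tc - lookback_s &
                        wb_metrics$t_start <= tc, ]
      w <- w[order(w$t_start), ]
      if (!nrow(w)) return(tb)
      busy <- w$n_calls >= 2
      # single-cycle dropouts flanked by qualifying cycles do not break the
      # run (a wingbeat straddling a behavioural transition can catch one
      # call); the documented tolerance is one cycle
      n <- length(busy)
      if (n >= 3) {
        fill <- !busy[2:(n - 1)] & busy[1:(n - 2)] & busy[3:n]
        busy[2:(n - 1)][fill] <- TRUE
      }
      # longest terminal run of cycles with >= 2 calls ending at the capture
      r <- rle(rev(busy))
      n_tail <- if (length(r$values) && r$values[1]) r$lengths[1] else 0L
      if (n_tail < min_consecutive) return(tb)
      onset <- w$t_start[nrow(w) - n_tail + 1]
      min(onset, tb)
    }
  )
  events
}

#' Partition the analysed span into behavioural segments
#'
#' Combines commute windows and capture events into a non-overlapping,
#' ordered segmentation covering the analysed record; uncovered spans are
#' labelled `"unknown"` (or `"gleaning"` by the caller where appropriate).
#'
#' @param commute Commute segments from [detect_commute()].
#' @param events Capture events with `t_approach_onset` (see
#'   [detect_approach_onset()]).
#' @param span `c(t0, t1)` of the analysed record.
#' @return Tibble `state`, `t_start`, `t_end` partitioning `span`.
#' @export
segment_record <- function(commute, events, span) {
  pieces <- dplyr::bind_rows(
    if (nrow(commute)) commute[, c("state", "t_start", "t_end")],
    if (nrow(events)) tibble::tibble(state = "approach",
                                     t_start = events$t_approach_onset,
                                     t_end = events$t_buzz_start),
    if (nrow(events)) tibble::tibble(state = "buzz",
                                     t_start = events$t_buzz_start,
                                     t_end = events$t_capture)
  )
  pieces <- pieces[order(pieces$t_start), ]
  pieces <- pieces[pieces$t_end > pieces$t_start, ]
  out <- list(); cur <- span[1]
  for (i in seq_len(nrow(pieces))) {
    if (pieces$t_start[i] > cur) {
      out[[length(out) + 1]] <- tibble::tibble(state = "unknown", t_start = cur,
                                               t_end = pieces$t_start[i])
    }
    out[[length(out) + 1]] <- pieces[i, ]
    cur <- max(cur, pieces$t_end[i])
  }
  if (cur < span[2]) {
    out[[length(out) + 1]] <- tibble::tibble(state = "unknown", t_start = cur,
                                             t_end = span[2])
  }
  dplyr::bind_rows(out)
}
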