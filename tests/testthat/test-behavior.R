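# Interval classification, buzz/capture events, aerial flags, commute
# windows and the approach-onset rule.

test_that("interval classes follow the half-open behavioural bins", {
  calls <- tibble::tibble(
    interval_prev_ms = c(NA, 5, 10, 14, 150, 250, 450, 700)
  )
  cls <- as.character(classify_intervals(calls)$interval_class)
  expect_equal(cls, c("unclassified", "buzzII", "buzzI", "multi_per_wb",
                      "one_per_wb", "one_per_2wb", "one_per_3wb",
                      "unclassified"))
  # alternative preset: 5-7 buzz II, 8-14 buzz I
  cls4 <- as.character(
    classify_intervals(tibble::tibble(interval_prev_ms = c(6, 7.5, 10)),
                       bins = interval_bins("fig4"))$interval_class
  )
  expect_equal(cls4, c("buzzII", "unclassified", "buzzI"))
  expect_error(classify_intervals(tibble::tibble(interval_prev_ms = -1)),
               "negative")
})

test_that("a buzz I + buzz II run defines one capture event", {
  # hand-built record: 5 slow calls, 10 buzz I intervals, 12 buzz II intervals
  iv <- c(NA, rep(200, 4), rep(10, 10), rep(5, 12))
  t <- cumsum(c(0, iv[-1])) / 1000
  calls <- tibble::tibble(call = seq_along(t), t_peak = t,
                          interval_prev_ms = iv)
  ev <- detect_buzzes(calls)
  expect_equal(nrow(ev), 1)
  # run opens at the call before the first fast interval (call 5)
  expect_equal(ev$first_call, 5)
  expect_equal(ev$t_capture, t[length(t)])
  # buzz II starts at the first call of the terminal sub-7-ms run
  expect_equal(ev$t_buzzII_start, t[16])
  expect_equal(ev$n_calls, 23)
})

test_that("commute-only records contain no capture events", {
  calls <- classify_intervals(
    tibble::tibble(t_peak = tight_commute_truth$calls$time_s) |>
      dplyr::mutate(interval_prev_ms = c(NA, diff(t_peak)) * 1000)
  )
  expect_equal(nrow(detect_buzzes(calls)), 0)
})

test_that("buzz I pauses under 100 ms do not split an event", {
  iv <- c(NA, rep(200, 3), rep(10, 6), 80, rep(5, 6))
  t <- cumsum(c(0, iv[-1])) / 1000
  calls <- tibble::tibble(t_peak = t, interval_prev_ms = iv)
  ev <- detect_buzzes(calls)
  expect_equal(nrow(ev), 1)
  iv2 <- c(NA, rep(200, 3), rep(10, 6), 150, rep(5, 6))
  t2 <- cumsum(c(0, iv2[-1])) / 1000
  ev2 <- detect_buzzes(tibble::tibble(t_peak = t2, interval_prev_ms = iv2))
  expect_equal(nrow(ev2), 2)
})

test_that("a full schedule-only night recovers every planned capture", {
  plan <- plan_foraging_night(n_captures = 12, commute_s = 30,
                              search_gap_s = 20, seed = 55)
  truth <- generate_flight(plan)
  calls <- tibble::tibble(t_peak = truth$calls$time_s,
                          sl_efd_db = truth$calls$sl_efd_db) |>
    dplyr::mutate(interval_prev_ms = c(NA, diff(t_peak)) * 1000) |>
    classify_intervals()
  ev <- detect_buzzes(calls)
  expect_equal(nrow(ev), 12)
  expect_equal(ev$t_capture, truth$captures$t_capture, tolerance = 1e-9)
  expect_equal(ev$t_buzzII_start, truth$captures$t_buzzII_start,
               tolerance = 1e-9)
})

test_that("aerial flags separate flying buzzes from grounded ones", {
  res <- mini_night
  expect_true(all(res$events$is_aerial))
  # a buzz while perched: cycles exist elsewhere but have feeble amplitude
  # around the event
  quiet <- res$cycles
  quiet$amp_ms2 <- 0.5
  expect_false(flag_aerial(res$events[1, ], quiet)$is_aerial)
  # no accelerometer overlap at all: unknown
  expect_true(is.na(
    flag_aerial(res$events[1, ], res$cycles,
                accel_span = c(1000, 2000))$is_aerial
  ))
})

test_that("gleaning plans emit sparse faint calls and no buzz", {
  plan <- flight_plan(flight_segment("gleaning", 30), seed = 66)
  truth <- generate_flight(plan)
  iv <- diff(truth$calls$time_s) * 1000
  expect_true(all(iv >= 200 & iv <= 500))
  expect_true(all(truth$calls$sl_efd_db == 60))
  expect_true(all(is.na(truth$calls$phase_deg)))
  calls <- tibble::tibble(t_peak = truth$calls$time_s,
                          interval_prev_ms = c(NA, iv)) |>
    classify_intervals()
  expect_equal(nrow(detect_buzzes(calls)), 0)
})

test_that("commute windows require 100 continuous buzz-free seconds", {
  plan <- flight_plan(flight_segment("commute", 120), seed = 21)
  truth <- generate_flight(plan)
  accel <- render_accel(truth)
  cyc <- detect_wingbeats(lowpass_accel(accel))
  calls <- tibble::tibble(t_peak = truth$calls$time_s) |>
    dplyr::mutate(interval_prev_ms = c(NA, diff(t_peak)) * 1000) |>
    classify_intervals()
  seg <- detect_commute(calls, cyc, detect_buzzes(calls), span = c(0, 120))
  expect_equal(nrow(seg), 1)
  expect_gte(seg$t_end - seg$t_start, 100)
  # an interrupting capture at t = 60 kills the window
  ev_mid <- tibble::tibble(t_buzz_start = 59.8, t_capture = 60)
  seg2 <- detect_commute(calls, cyc, ev_mid, span = c(0, 120))
  expect_equal(nrow(seg2), 0)
})

test_that("approach onset lands on the first sustained multi-call cycle", {
  res <- mini_night
  truth <- res$truth
  ap <- truth$segments[truth$segments$state == "approach", ]
  # first approach sub-segment of each capture sequence
  ap_start <- ap$t_start[seq(1, nrow(ap), by = 2)]
  err <- res$events$t_approach_onset - ap_start
  # within one wingbeat cycle (~0.14 s) for most events; the rule's
  # documented tolerance is +/- 1 cycle
  expect_lt(median(abs(err)), 0.15)
  expect_true(all(res$events$t_approach_onset <= res$events$t_buzz_start))
  # degenerate fast attack: no approach -> onset at buzz start
  ev <- tibble::tibble(t_capture = 10, t_buzz_start = 9.8)
  wb <- tibble::tibble(t_start = seq(5, 9.9, 0.1), t_end = seq(5.1, 10, 0.1),
                       n_calls = 1L)
  out <- detect_approach_onset(ev, wb)
  expect_equal(out$t_approach_onset, 9.8)
})

test_that("segmentation partitions the analysed span", {
  seg <- mini_night$segments
  expect_equal(seg$t_start[1], 0)
  expect_true(all(abs(seg$t_start[-1] - seg$t_end[-nrow(seg)]) < 1e-9))
  expect_true(all(seg$t_end > seg$t_start))
})
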