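# Call-to-wingbeat joins, per-wingbeat energy metrics, capture alignment,
# circular statistics, phase histograms, level-vs-interval.

test_that("call phases are recovered from the accelerometer to a few degrees", {
  truth <- tight_commute_truth
  filt <- lowpass_accel(tight_commute_accel)
  cyc <- detect_wingbeats(filt)
  ph <- compute_phase(filt, cyc)
  calls <- assign_phase(
    tibble::tibble(t_peak = truth$calls$time_s), ph
  )
  ok <- !is.na(calls$phase_deg)
  err <- circ_diff(calls$phase_deg[ok], truth$calls$phase_deg[ok])
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(err)), 15)
  # the recovered circular median matches the truth sample's median
  expect_lt(abs(circ_diff(circ_median(calls$phase_deg[ok]),
                          brute_circ_median(truth$calls$phase_deg[ok]))), 5)
})

test_that("calls in masked spans get missing phase", {
  ph <- tibble::tibble(time_s = seq(0, 1, 1e-3),
                       phase_deg = NA_real_, valid = FALSE)
  out <- assign_phase(tibble::tibble(t_peak = 0.5), ph)
  expect_true(is.na(out$phase_deg))
})

test_that("per-wingbeat summed energy follows energy-domain arithmetic", {
  cyc <- tibble::tibble(cycle = 1:3, t_start = c(0, 1, 2), t_mid = c(0.5, 1.5, 2.5),
                        t_end = c(1, 2, 3), duration_s = 1, freq_hz = 1,
                        amp_ms2 = 10)
  calls <- tibble::tibble(t_peak = c(0.2, 0.6, 1.5, 3.5),
                          sl_efd_db = c(70, 70, 82, 60))
  m <- per_wingbeat_metrics(calls, cyc)
  # two 70 dB calls sum to 73.01 dB
  expect_equal(m$summed_efd_db[1], 10 * log10(2 * 1e7), tolerance = 1e-9)
  # a single call's summed EFD is its own level
  expect_equal(m$summed_efd_db[2], 82)
  # empty cycle: sentinel NA, not -Inf
  expect_true(is.na(m$summed_efd_db[3]))
  expect_equal(m$n_calls, c(2L, 1L, 0L))
  # the call outside every cycle lands in the uncycled bucket
  expect_equal(attr(m, "uncycled"), 4L)
  # summed EFD >= the loudest member call
  expect_gte(m$summed_efd_db[1], 70)
  expect_gte(m$summed_efd_db[2], 82)
})

test_that("a buzz cycle of faint calls sums ~20 dB below a loud single call", {
  cyc <- tibble::tibble(cycle = 1:2, t_start = c(0, 1), t_mid = c(0.5, 1.5),
                        t_end = c(1, 2), duration_s = 1, freq_hz = 1,
                        amp_ms2 = 10)
  calls <- tibble::tibble(
    t_peak = c(0.5, seq(1.05, 1.95, length.out = 11)),
    sl_efd_db = c(82, rep(52, 11))
  )
  m <- per_wingbeat_metrics(calls, cyc)
  # 11 calls at -30 dB: energy sum gains 10 log10(11) = 10.4 dB
  expect_equal(m$summed_efd_db[1] - m$summed_efd_db[2], 30 - 10 * log10(11),
               tolerance = 1e-9)
})

test_that("per-cycle energy sums conserve total call energy", {
  res <- mini_night
  m <- res$wb_metrics
  assigned <- setdiff(seq_len(nrow(res$calls)), attr(m, "uncycled"))
  tot_calls <- sum(10^(res$calls$sl_efd_db[assigned] / 10))
  tot_cycles <- sum(10^(m$summed_efd_db[!is.na(m$summed_efd_db)] / 10))
  expect_equal(tot_cycles, tot_calls, tolerance = 1e-9)
})

test_that("capture alignment shows decoupling: more calls, less energy", {
  al <- tidy(mini_night$alignment)
  expect_equal(nrow(al), 10)
  expect_equal(al$wb_index, -10:-1)
  first <- al[al$wb_index == -10, ]
  last <- al[al$wb_index == -1, ]
  expect_gt(last$mean_calls_per_wb, first$mean_calls_per_wb)
  expect_lt(last$mean_summed_efd_db, first$mean_summed_efd_db)
  # calls per wingbeat at the capture cycle matches the schedule's truth
  truth <- mini_night$truth
  truth_last <- vapply(truth$captures$t_capture, function(tc) {
    cyc <- mini_night$wb_metrics
    i <- which(cyc$t_start <= tc & cyc$t_end > tc)
    sum(truth$calls$time_s >= cyc$t_start[i] & truth$calls$time_s < cyc$t_end[i])
  }, numeric(1))
  expect_lt(abs(last$mean_calls_per_wb - mean(truth_last)), 1)
})

test_that("a constant-commute control is flat at one call per wingbeat", {
  filt <- lowpass_accel(tight_commute_accel)
  cyc <- detect_wingbeats(filt)
  calls <- tibble::tibble(t_peak = tight_commute_truth$calls$time_s,
                          sl_efd_db = 82)
  m <- per_wingbeat_metrics(calls, cyc)
  ev <- tibble::tibble(t_capture = cyc$t_end[nrow(cyc)] - 0.01)
  al <- tidy(align_to_capture(ev, m))
  expect_true(all(al$mean_calls_per_wb == 1))
  expect_true(all(abs(al$mean_summed_efd_db - 82) < 1e-9))
})

test_that("circular median matches the brute-force minimiser", {
  set.seed(11)
  for (center in c(20, 176, 340)) {
    x <- (center + 40 * rnorm(400)) %% 360
    expect_lt(abs(circ_diff(circ_median(x), brute_circ_median(x))), 0.5)
  }
  # large-sample binned path agrees too
  x <- (176 + 74 * rnorm(5000)) %% 360
  expect_lt(abs(circ_diff(circ_median(x), brute_circ_median(x))), 0.5)
})

test_that("circular quartiles recover the generator's quartile range", {
  set.seed(12)
  # wrapped normal with quartiles at 135 and 235 (sd ~ 74 deg around 185)
  x <- (185 + 74.1 * rnorm(4000)) %% 360
  q <- circ_quartiles(x)
  expect_lt(abs(circ_diff(q[["q25"]], 135)), 10)
  expect_lt(abs(circ_diff(q[["q75"]], 235)), 10)
})

test_that("phase histograms are flat for uniform phases and respect min size", {
  set.seed(13)
  calls <- tibble::tibble(
    phase_deg = runif(3600, 0, 360),
    interval_class = factor("one_per_wb",
                            levels = levels(classify_intervals(
                              tibble::tibble(interval_prev_ms = 150))$interval_class))
  )
  h <- phase_histogram(calls)
  counts <- h$histogram$count
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  # a class with < 10 calls keeps counts but no normalised curve
  small <- calls[1:5, ]
  small$interval_class <- factor("buzzII", levels = levels(calls$interval_class))
  h2 <- phase_histogram(small)
  expect_true(all(is.na(h2$histogram$normalized)))
  expect_equal(sum(h2$histogram$count), 5)
})

test_that("level-vs-interval localises the generator's source-level drop", {
  li <- mini_night$level_interval
  expect_false(is.null(li$transition_band_ms))
  # the flagged band must sit between the buzz/approach-triad intervals and
  # the loud dyad/search intervals and separate faint from loud medians
  expect_gte(li$transition_band_ms[1], 14)
  expect_lte(li$transition_band_ms[2], 150)
  expect_lte(li$transition_band_ms[1], li$transition_band_ms[2])
  bins <- li$bins[!is.na(li$bins$median_sl_efd_db), ]
  below <- bins$median_sl_efd_db[bins$interval_hi_ms <= li$transition_band_ms[1]]
  above <- bins$median_sl_efd_db[bins$interval_lo_ms >= li$transition_band_ms[2]]
  expect_gt(min(above) - max(below), 10)
  # no loud calls at short intervals (exclusion region)
  calls <- mini_night$calls
  loud <- calls$sl_efd_db > 75 & !is.na(calls$interval_prev_ms)
  expect_true(all(calls$interval_prev_ms[loud] >= 40))
})

test_that("flat levels yield no transition band", {
  calls <- tibble::tibble(interval_prev_ms = seq(10, 500, by = 10),
                          sl_efd_db = 80)
  li <- level_vs_interval(calls)
  expect_null(li$transition_band_ms)
  med <- li$bins$median_sl_efd_db
  expect_true(all(med[!is.na(med)] == 80))
})

test_that("the calls-per-second histogram integrates to the call count", {
  rh <- mini_night$rate_hist
  expect_equal(sum(rh$calls_per_s * rh$n_seconds), nrow(mini_night$calls))
})
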