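# High-pass filtering, call detection, -6 dB window measurement and
# source-level calibration.

test_that("10 kHz high-pass passes the call band and kills low frequencies", {
  g40 <- 20 * log10(mid_rms(highpass_audio(tone_audio(40000))) /
                      mid_rms(tone_audio(40000)))
  expect_gt(g40, -1)
  g1 <- 20 * log10(mid_rms(highpass_audio(tone_audio(1000, dur = 0.2))) /
                     mid_rms(tone_audio(1000, dur = 0.2)))
  expect_lt(g1, -70)
  dc <- tone_audio(0, dur = 0.2, amp = 0)
  dc$pressure <- dc$pressure + 0.5
  n <- length(dc$pressure)
  expect_lt(abs(mean(highpass_audio(dc)$pressure[round(n / 2):n])), 1e-3)
})

test_that("detector recovers every synthetic commute call to sub-ms accuracy", {
  truth <- tight_commute_truth
  aud <- render_audio(truth)  # SNR ~ 40 dB for search-level calls
  calls <- analyze_audio(aud)
  expect_equal(nrow(calls), nrow(truth$calls))
  expect_lt(max(match_calls(truth$calls, calls)), 5e-4)
})

test_that("pure noise yields zero detections at the default threshold", {
  set.seed(77)
  noise <- structure(list(pressure = rnorm(187500 * 2, 0, 20e-6 * 10^(40 / 20)),
                          fs = 187500, clip_db = 121, clipped_fraction = 0),
                     class = "tag_audio")
  expect_equal(nrow(detect_calls(highpass_audio(noise))), 0)
})

test_that("a 5 ms buzz II train is fully resolved", {
  plan <- flight_plan(flight_segment("buzzII", 0.12, interval_ms = c(5, 5)),
                      seed = 12)
  truth <- generate_flight(plan)
  aud <- render_audio(truth)
  calls <- analyze_audio(aud)
  expect_equal(nrow(calls), nrow(truth$calls))
  iv <- diff(calls$t_peak) * 1000
  expect_true(all(abs(iv - 5) < 0.5))
})

test_that("refractory at or above the buzz II band is rejected", {
  expect_error(detect_calls(capture_audio, refractory_ms = 4), "buzz II")
  expect_error(run_pipeline(plan = capture_plan, refractory_ms = 5), "refractory")
})

test_that("detection count is monotonically non-increasing in threshold", {
  a <- highpass_audio(capture_audio)
  n <- vapply(c(10, 20, 30, 40), function(th) {
    nrow(detect_calls(a, threshold_db = th))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("-6 dB window EFD matches the hand-computed oracle", {
  # 3 ms constant-envelope 40 kHz call at 2 Pa RMS:
  # EFD = 10 log10(2^2 * 0.003 / (20e-6)^2) = 74.77 dB re 20 uPa^2 s
  fs <- 187500
  t <- seq(0, 0.003 - 1 / fs, by = 1 / fs)
  p <- numeric(fs * 0.05)
  p[2000 + seq_along(t)] <- 2 * sqrt(2) * sin(2 * pi * 40000 * t)
  a <- structure(list(pressure = p, fs = fs, clip_db = 121,
                      clipped_fraction = 0), class = "tag_audio")
  det <- tibble::tibble(call = 1L, t_peak = (2000 + length(t) / 2) / fs)
  m <- measure_calls(a, det)
  oracle <- 10 * log10(2^2 * 0.003 / (20e-6)^2)
  expect_equal(m$efd_apparent_db, oracle, tolerance = 0.005)
  expect_equal(m$duration_6db_ms, 3, tolerance = 0.1)
  # halving the pressure lowers EFD by 6.02 dB
  a2 <- a; a2$pressure <- a2$pressure / 2
  m2 <- measure_calls(a2, det)
  expect_equal(m$efd_apparent_db - m2$efd_apparent_db, 20 * log10(2),
               tolerance = 1e-6)
})

test_that("Hann-enveloped calls have an interior -6 dB duration", {
  truth <- tight_commute_truth
  aud <- render_audio(truth)
  calls <- analyze_audio(aud)
  expect_true(all(calls$duration_6db_ms < 3))
  expect_true(all(calls$duration_6db_ms > 1))
  # energy-window mode never exceeds the full-call energy
  a <- highpass_audio(aud)
  det <- calls[, c("call", "t_peak")]
  env_m <- measure_calls(a, det, mode = "envelope")
  full <- measure_calls(a, det, max_window_ms = 6, mode = "energy")
  expect_true(all(env_m$efd_apparent_db <= calls$efd_apparent_db + 6.1))
})

test_that("source levels are recovered within 1 dB on clean synthetics", {
  truth <- capture_truth
  aud <- capture_audio
  calls <- analyze_audio(aud)
  dt <- match_calls(truth$calls, calls)
  idx <- vapply(truth$calls$time_s,
                function(tt) which.min(abs(calls$t_peak - tt)), integer(1))
  ok <- dt < 5e-4
  err <- calls$sl_efd_db[idx[ok]] - truth$calls$sl_efd_db[ok]
  expect_lt(max(abs(err)), 1)
})

test_that("calibration offsets are exact arithmetic", {
  expect_identical(apparent_to_source(74.8), 88.8)
  expect_identical(efd_to_rms(88.8), 113.8)
  expect_identical(apparent_to_source(0), 14)
  expect_identical(efd_to_rms(apparent_to_source(0)), 39)
  # the printed 25 dB offset is the fixed-3-ms conversion, -10 log10(0.003)
  expect_equal(rms_offset_for_duration(0.003), 25.2, tolerance = 0.02)
})

test_that("noisy-epoch masks suppress detections inside them", {
  a <- highpass_audio(capture_audio)
  all_calls <- detect_calls(a)
  masked <- detect_calls(a, exclude = cbind(0, 1.5))
  expect_true(all(masked$t_peak > 1.5))
  expect_lt(nrow(masked), nrow(all_calls))
})

test_that("microphone response compensation flattens a known tilt", {
  a <- tone_audio(40000, dur = 0.02)
  resp <- tibble::tibble(freq_hz = c(0, 100000), gain_db = c(6, 6))
  flat <- compensate_mic_response(a, resp)
  expect_equal(mid_rms(flat) / mid_rms(a), 10^(-6 / 20), tolerance = 0.01)
})
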