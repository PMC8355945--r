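# Shared fixtures, built once per test run. All are seeded and cheap except
# the mini foraging night, which exercises the full audio path.

# 10 s of noise-free commuting flight at 7 Hz, tight phase jitter
tight_commute_plan <- flight_plan(
  flight_segment("commute", 10, phase_spread_deg = 10), seed = 101
)
tight_commute_truth <- generate_flight(tight_commute_plan)
tight_commute_accel <- render_accel(tight_commute_truth)

# one capture sequence with a buzz, audio rendered
capture_plan <- flight_plan(
  dplyr::bind_rows(
    flight_segment("search", 1.5),
    flight_segment("approach", 1, calls_per_wb = 2, phase_spread_deg = 10),
    flight_segment("buzzI", 0.12),
    flight_segment("buzzII", 0.05)
  ),
  seed = 202
)
capture_truth <- generate_flight(capture_plan)
capture_audio <- render_audio(capture_truth)

# small foraging night through the full pipeline (audio path end to end)
mini_night_plan <- plan_foraging_night(n_captures = 6, commute_s = 25, seed = 303)
mini_night <- run_pipeline(plan = mini_night_plan)

# match each truth call to the nearest detection; returns dt in seconds
match_calls <- function(truth_calls, detected) {
  vapply(truth_calls$time_s,
         function(tt) min(abs(detected$t_peak - tt)), numeric(1))
}

# brute-force circular median: dense grid minimiser of mean circular
# absolute deviation (independent of the package's estimator)
brute_circ_median <- function(theta, step = 0.05) {
  grid <- seq(0, 360 - step, by = step)
  dev <- vapply(grid, function(m) {
    d <- abs(theta - m) %% 360
    mean(pmin(d, 360 - d))
  }, numeric(1))
  grid[which.min(dev)]
}

# circular difference in (-180, 180]
circ_diff <- function(a, b) ((a - b + 180) %% 360) - 180

# probe-tone gain of the accelerometer low-pass at one frequency
probe_gain <- function(f_hz, fs = 1000, dur = 20) {
  t <- seq(0, dur, by = 1 / fs)
  x <- tibble::tibble(time_s = t, acc_z_ms2 = sin(2 * pi * f_hz * t))
  y <- lowpass_accel(x)$acc_z_ms2
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  max(abs(y[mid]))
}

tone_audio <- function(f_hz, dur = 0.05, amp = 1, fs = 187500) {
  t <- seq(0, dur, by = 1 / fs)
  structure(list(pressure = amp * sin(2 * pi * f_hz * t), fs = fs,
                 clip_db = 121, clipped_fraction = 0), class = "tag_audio")
}

mid_rms <- function(a) {
  n <- length(a$pressure)
  sqrt(mean(a$pressure[round(n * 0.5):n]^2))
}
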