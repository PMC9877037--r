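test_that("track config validation names the offending field", {
  expect_error(track_config(track_length = -1), "track_length")
  expect_error(track_config(error_rate = 1), "error_rate")
  expect_error(track_config(runs_per_reward = 0), "runs_per_reward")
  expect_error(track_config(pause_range = c(3, 1)), "pause_range")
})

test_that("error-free session rewards every fourth run and flags no errors", {
  cfg <- track_config(n_runs = 8, max_duration_s = NULL, error_rate = 0)
  beh <- simulate_track_session(cfg, seed = 1)
  expect_length(attr(beh, "rewards"), 2)
  runs <- attr(beh, "runs")
  expect_equal(nrow(runs), 8)
  expect_false(any(runs$error))
  expect_true(all(attr(beh, "trials")$correct))
})

test_that("identical config and seed reproduce the session bit-identically", {
  cfg <- track_config(n_runs = 6, max_duration_s = NULL)
  a <- simulate_track_session(cfg, seed = 7)
  b <- simulate_track_session(cfg, seed = 7)
  expect_identical(a$x_cm, b$x_cm)
  expect_identical(a$distance_cm, b$distance_cm)
  c <- simulate_track_session(cfg, seed = 8)
  expect_false(identical(a$x_cm, c$x_cm))
})

test_that("traversal durations match the kinematic expectation", {
  cfg <- track_config(n_runs = 100, max_duration_s = NULL, mean_speed = 20,
                      speed_cv = 0.2, pause_range = c(0, 0), error_rate = 0,
                      hesitation_rate = 0, stop_rate = 0, sortie_rate = 0,
                      trial_speed_cv = 0)
  beh <- simulate_track_session(cfg, seed = 3)
  runs <- attr(beh, "runs")
  durs <- diff(c(0, runs$t_end))
  expect_equal(mean(durs), 134 / 20, tolerance = 0.2)
})

test_that("position stays on the track and clocks reset together", {
  beh <- small_track()
  expect_true(all(beh$x_cm >= 0 & beh$x_cm <= 134))
  expect_true(all(beh$elapsed_s >= 0))
  expect_true(all(beh$distance_cm >= 0))
  # reset coupling: elapsed time ~ 0 exactly where distance ~ 0
  at_reset <- abs(beh$elapsed_s) < 1e-9
  expect_true(all(beh$distance_cm[at_reset] < 1))
})

test_that("distance is non-decreasing within a trial and resets at trials", {
  beh <- small_track()
  for (tr in unique(beh$trial_id[beh$trial_id > 0])) {
    d <- beh$distance_cm[beh$trial_id == tr]
    expect_true(all(diff(d) >= -1e-9))
    expect_lt(d[1], 2)
  }
})

test_that("clean ideal four-run block accumulates ~4 track lengths", {
  cfg <- track_config(n_runs = 4, max_duration_s = NULL, error_rate = 0,
                      hesitation_rate = 0, stop_rate = 0, sortie_rate = 0,
                      turn_jitter_cm = 0, path_noise_cm = 0,
                      pause_range = c(0, 0))
  beh <- simulate_track_session(cfg, seed = 4)
  # departure threshold (5 cm) trims the first few centimeters
  expect_equal(max(beh$distance_cm), 4 * 134, tolerance = 0.03)
})

test_that("programmed full reversals are flagged as error runs", {
  cfg <- track_config(n_runs = 40, max_duration_s = NULL, error_rate = 0.5,
                      hesitation_rate = 0, stop_rate = 0, sortie_rate = 0)
  beh <- simulate_track_session(cfg, seed = 5)
  runs <- attr(beh, "runs")
  # about half the runs should carry an error; binomial 99% margin
  expect_gt(sum(runs$error), 10)
  expect_lt(sum(runs$error), 30)
  trials <- attr(beh, "trials")
  expect_true(any(!trials$correct, na.rm = TRUE))
})

test_that("hesitations and sorties are not scored as errors", {
  cfg <- track_config(n_runs = 20, max_duration_s = NULL, error_rate = 0,
                      hesitation_rate = 3, sortie_rate = 1.5)
  beh <- simulate_track_session(cfg, seed = 6)
  expect_false(any(attr(beh, "runs")$error))
})

test_that("open field stays in bounds and covers the arena", {
  beh <- simulate_open_field(c(45, 45), duration_s = 600, seed = 2)
  expect_equal(nrow(beh), 18000)
  expect_true(all(beh$x_cm >= 0 & beh$x_cm <= 45))
  expect_true(all(beh$y_cm >= 0 & beh$y_cm <= 45))
  # speed distribution spans rest and locomotion
  expect_gt(mean(beh$speed_cm_s < 2), 0.05)
  expect_gt(mean(beh$speed_cm_s > 2), 0.3)
  # occupancy over a coarse 3x3 grid is nonzero everywhere
  gx <- cut(beh$x_cm, 3); gy <- cut(beh$y_cm, 3)
  expect_true(all(table(gx, gy) > 0))
})
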