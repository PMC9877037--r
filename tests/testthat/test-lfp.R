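fs <- 1000

test_that("Morlet spectrogram puts ridges at the oscillation frequency", {
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ws <- wavelet_spectrogram(sin(2 * pi * 8 * t), fs, freqs = 4:14)
  ridge <- ws$freqs[apply(ws$power, 2, which.max)]
  inner <- t > 0.5 & t < 3.5
  expect_true(all(ridge[inner] == 8))
  # frequency step: 6 Hz then 10 Hz
  x2 <- c(sin(2 * pi * 6 * t[t < 2]), sin(2 * pi * 10 * t[t >= 2]))
  ws2 <- wavelet_spectrogram(x2, fs, freqs = seq(4, 14, 0.5))
  r2 <- ws2$freqs[apply(ws2$power, 2, which.max)]
  expect_equal(median(r2[t > 0.5 & t < 1.5]), 6)
  expect_equal(median(r2[t > 2.5 & t < 3.5]), 10)
})

test_that("wavelet ridge tracks a chirp within 0.5 Hz", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  chirp <- sin(2 * pi * (4 * t + 0.4 * t^2))  # 4 -> 12 Hz linear sweep
  ws <- wavelet_spectrogram(chirp, fs, freqs = seq(3, 14, 0.25))
  ridge <- ws$freqs[apply(ws$power, 2, which.max)]
  inst <- 4 + 0.8 * t
  inner <- t > 1 & t < 9
  expect_lt(max(abs(ridge - inst)[inner]), 0.5)
})

test_that("moving-window spectra resolve the dominant frequency", {
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  mw <- movingwin_spectrum(sin(2 * pi * 8 * t), fs)
  expect_true(all(abs(mw$dominant_freq - 8) <= 0.25))
  # step count: floor((len/fs - window)/step) + 1
  expect_equal(length(mw$times), floor((6 - 2) / 0.01) + 1)
  # white noise: dominant frequency spreads across the band
  set.seed(1)
  mwn <- movingwin_spectrum(rnorm(6 * fs), fs)
  expect_gt(diff(range(mwn$dominant_freq)), 5)
})

test_that("oscillation strength hits its analytic anchors and is scale-free", {
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 8 * t)
  os <- oscillation_strength(sine, fs)
  expect_equal(as.numeric(os), 1, tolerance = 0.02)
  expect_equal(attr(os, "peak_freq"), 8)
  # amplitude scaling leaves OS unchanged; bounded in [0, 1]
  expect_equal(as.numeric(oscillation_strength(50 * sine, fs)),
               as.numeric(os))
  set.seed(2)
  mix <- replicate(5, as.numeric(
    oscillation_strength(rnorm(5 * fs) + runif(1, 0, 3) * sine, fs)))
  expect_true(all(mix >= 0 & mix <= 1))
  # OS grows with sine amplitude against a fixed noise floor
  set.seed(3)
  noise <- rnorm(5 * fs)
  vals <- vapply(c(0.5, 1, 2, 4),
                 function(a) as.numeric(oscillation_strength(
                   noise + a * sine, fs)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(oscillation_strength(sine[1:1000], fs), "5 s")
})

test_that("band power portions reflect constructed amplitude changes", {
  dur <- 60
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  set.seed(4)
  base_theta <- 40 * sin(2 * pi * 7.5 * tt)
  noise <- 15 * thetacode:::one_over_f_noise(dur * fs, 1)
  stim_idx <- rep(rep(c(TRUE, FALSE), each = 5 * fs), 6)
  x <- base_theta * ifelse(stim_idx, 2, 1) + noise  # theta amplitude x2
  stim <- lapply(seq(0, 50, 10), function(s) list(start = s, end = s + 5))
  bl <- lapply(seq(5, 55, 10), function(s) list(start = s, end = s + 5))
  bp <- band_power_portions(x, fs, stim, bl)
  expect_equal(unname(bp["theta"]), 4, tolerance = 0.15)
  expect_lt(abs(bp["gamma_slow"] - 1), 0.5)
  # identical epoch sets: every portion exactly 1
  bp2 <- band_power_portions(x, fs, stim, stim)
  expect_equal(unname(bp2), rep(1, 6))
  expect_named(bp, c("delta", "theta", "alpha_beta", "gamma_slow",
                     "gamma_fast", "hfo"))
})

test_that("theta frequency tracks speed only when it is speed-coupled", {
  beh <- small_track()
  dur <- floor(max(beh$time_s))
  plan <- lfp_plan(duration_s = dur, fs = 500, theta_speed_gain = 0.08,
                   theta_amp = 50, noise_amp = 15)
  sim <- simulate_lfp(plan, speed = beh$speed_cm_s, seed = 5)
  mw <- movingwin_spectrum(sim$lfp$samples, 500)
  sp <- stats::approx(beh$time_s, beh$speed_cm_s, xout = mw$times,
                      rule = 2)$y
  run <- sp > 5
  r <- theta_speed_relation(mw$dominant_freq[run], sp[run])
  expect_gt(r$r2, 0.3)
  # 8 Hz pacing: frequency pinned, no speed relation
  plan2 <- lfp_plan(duration_s = dur, fs = 500, theta_amp = 50,
                    noise_amp = 5,
                    stim_epochs = list(list(start = 0, end = dur,
                                            pattern = "pace8")))
  sim2 <- simulate_lfp(plan2, speed = beh$speed_cm_s, seed = 6)
  mw2 <- movingwin_spectrum(sim2$lfp$samples, 500)
  sp2 <- stats::approx(beh$time_s, beh$speed_cm_s, xout = mw2$times,
                       rule = 2)$y
  r2 <- suppressWarnings(
    theta_speed_relation(mw2$dominant_freq[sp2 > 5], sp2[sp2 > 5]))
  expect_true(is.na(r2$r2) || r2$r2 < 0.05)
  expect_warning(r3 <- theta_speed_relation(rep(8, 100), runif(100)),
                 "constant")
  expect_true(is.na(r3$r2))
})

test_that("quiet rest is flagged where delta dominates theta", {
  tt <- seq(0, 40 - 1 / fs, by = 1 / fs)
  set.seed(7)
  x <- c(60 * sin(2 * pi * 8 * tt[tt < 20]),
         60 * sin(2 * pi * 2.5 * tt[tt >= 20])) + rnorm(40 * fs, 0, 5)
  m <- quiet_rest_mask(x, fs)
  expect_length(m, length(x))
  expect_lt(mean(m[tt < 18]), 0.2)
  expect_gt(mean(m[tt > 22]), 0.8)
  # stationary statistics: about half the samples sit below the z-scored mean
  m2 <- quiet_rest_mask(rnorm(30 * fs), fs)
  expect_equal(mean(m2), 0.5, tolerance = 0.15)
})

test_that("ripple detection recovers injected bursts without false alarms", {
  plan <- lfp_plan(duration_s = 60, fs = fs, theta_amp = 30,
                   ripple_times = seq(5, 50, 5), ripple_amp_sd = 8)
  sim <- simulate_lfp(plan, seed = 8)
  expect_length(sim$truth$ripple_times, 10)
  ev <- detect_ripples(sim$lfp$samples, fs)
  hits <- vapply(sim$truth$ripple_times,
                 function(t0) any(abs(ev$peak_time_s - t0) <= 0.01),
                 logical(1))
  expect_gte(sum(hits), 9)
  expect_true(all(ev$peak_z >= 4))
  expect_true(all(ev$width_s > 0))
  # burst-free noise: no events in 10 minutes
  set.seed(9)
  fa <- detect_ripples(rnorm(600 * fs), fs)
  expect_lte(nrow(fa), 1)
  # two bursts 20 ms apart merge under the 30-ms spacing rule
  plan2 <- lfp_plan(duration_s = 20, fs = fs, theta_amp = 30,
                    ripple_times = c(10, 10.02), ripple_amp_sd = 8)
  sim2 <- simulate_lfp(plan2, seed = 10)
  ev2 <- detect_ripples(sim2$lfp$samples, fs)
  expect_equal(nrow(ev2[abs(ev2$peak_time_s - 10) < 0.05, ]), 1)
  expect_warning(out <- detect_ripples(sim2$lfp$samples, fs,
                                       rest_mask = rep(FALSE, 20 * fs)),
                 "empty")
  expect_equal(nrow(out), 0)
})

test_that("cross-channel correlation finds lags and nulls out on noise", {
  set.seed(11)
  plan <- lfp_plan(duration_s = 20, fs = fs, theta_amp = 40, noise_amp = 10)
  a <- simulate_lfp(plan, seed = 12)$lfp$samples
  xc <- cross_channel_xcorr(a, a, fs)
  expect_equal(xc$peak_lag_s, 0)
  expect_equal(xc$peak_cor, 1, tolerance = 1e-6)
  b <- c(rep(0, 10), a[1:(length(a) - 10)])  # 10 ms delayed copy
  xc2 <- cross_channel_xcorr(a, b, fs)
  expect_equal(xc2$peak_lag_s, 0.01, tolerance = 1e-9)
  peaks <- replicate(20, {
    x1 <- rnorm(4 * fs); x2 <- rnorm(4 * fs)
    cross_channel_xcorr(x1, x2, fs)$peak_cor
  })
  expect_lt(mean(peaks), 0.2)
})

test_that("phase consistency separates phase-reset from free-running epochs", {
  onsets <- seq(5, 110, 10)
  plan <- lfp_plan(duration_s = 120, fs = fs, theta_amp = 40,
                   noise_amp = 8,
                   stim_epochs = lapply(onsets, function(s)
                     list(start = s, end = s + 5, pattern = "pace8")))
  sim <- simulate_lfp(plan, seed = 13)
  r <- epoch_phase_consistency(sim$lfp$samples, fs, onsets,
                               band = c(6, 10))
  expect_gt(r$r, 0.9)
  # free-running theta at a non-commensurate frequency: phases disperse
  plan2 <- lfp_plan(duration_s = 120, fs = fs, theta_base_freq = 7.13,
                    theta_amp = 40, noise_amp = 8)
  sim2 <- simulate_lfp(plan2, seed = 14)
  r2 <- epoch_phase_consistency(sim2$lfp$samples, fs,
                                seq(3, 113, length.out = 12) +
                                  runif(12, 0, 1), band = c(6, 10))
  expect_lt(r2$r, 0.5)
  expect_error(epoch_phase_consistency(sim$lfp$samples, fs, 5), "2 epochs")
})

test_that("scrambled epochs lose theta-band concentration", {
  plan <- lfp_plan(duration_s = 30, fs = fs, theta_amp = 50, noise_amp = 10,
                   stim_epochs = list(list(start = 10, end = 20,
                                           pattern = "scrambled")))
  sim <- simulate_lfp(plan, seed = 15)
  x <- sim$lfp$samples
  theta_share <- function(seg) {
    mw <- thetacode:::movingwin_fft(seg, fs, 2, 0.05)
    psd <- rowMeans(mw$power)
    sum(psd[mw$freqs >= 4 & mw$freqs <= 12]) /
      sum(psd[mw$freqs >= 1 & mw$freqs <= 250])
  }
  inside <- theta_share(x[(10 * fs + 1):(20 * fs)])
  outside <- theta_share(x[1:(10 * fs)])
  expect_lt(inside, outside)
  # random-frequency epochs record their realized frequency
  plan2 <- lfp_plan(duration_s = 30, fs = fs, theta_amp = 50,
                    stim_epochs = list(list(start = 5, end = 10,
                                            pattern = "random_freq")))
  sim2 <- simulate_lfp(plan2, seed = 16)
  f <- sim2$truth$epochs[[1]]$frequency
  expect_true(f >= 4 && f <= 12)
  mw <- movingwin_spectrum(sim2$lfp$samples[(5 * fs + 1):(10 * fs)], fs)
  expect_equal(median(mw$dominant_freq), f, tolerance = 0.3)
})
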