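#' LFP simulation plan
#'
#' Describes a synthetic hippocampal LFP: a 1/f background, a theta component
#' whose instantaneous frequency follows running speed, optional optogenetic
#' stimulation epochs that replace the theta component (8 Hz pacing,
#' variance-matched broadband "scrambled" drive, or one random theta-band
#' frequency per epoch), and sharp-wave-ripple bursts injected at given
#' times during the session.
#'
#' @param duration_s Signal duration, s.
#' @param fs Sampling rate, Hz (>= 1000 recommended; must be >= 500 for
#'   ripple work).
#' @param theta_base_freq Theta frequency at zero speed, Hz (default 6).
#' @param theta_speed_gain Slope of theta frequency on running speed,
#'   Hz per cm/s (default 0.05). Free parameters of the generator, not
#'   measured values.
#' @param theta_amp Theta amplitude, uV (default 50).
#' @param noise_amp SD of the 1/f background, uV (default 20).
#' @param noise_exponent Spectral slope of the background (power ~ 1/f^a,
#'   default 1).
#' @param stim_epochs List of `list(start, end, pattern)` with pattern in
#'   `"none"`, `"pace8"`, `"scrambled"`, `"random_freq"`; epochs must be
#'   non-overlapping and inside the signal.
#' @param ripple_times Times (s) at which ripple bursts are injected.
#' @param ripple_freq Ripple carrier frequency, Hz, in 150-250 (default 180).
#' @param ripple_amp_sd Ripple peak amplitude in units of the background SD
#'   (default 8).
#' @param ripple_env_sd SD of the Gaussian ripple envelope, s (default
#'   0.015, i.e. ~ 50 ms events).
#' @return An `lfp_plan` object.
#' @export
lfp_plan <- function(duration_s, fs = 1000, theta_base_freq = 6,
                     theta_speed_gain = 0.05, theta_amp = 50,
                     noise_amp = 20, noise_exponent = 1,
                     stim_epochs = list(), ripple_times = numeric(0),
                     ripple_freq = 180, ripple_amp_sd = 8,
                     ripple_env_sd = 0.015) {
  check_that(duration_s > 0, "must be > 0", "duration_s")
  check_that(fs >= 250, "sampling rate too low", "fs")
  check_that(ripple_freq >= 150 && ripple_freq <= 250,
             "must be within 150-250 Hz", "ripple_freq")
  if (length(stim_epochs) > 0) {
    se <- t(vapply(stim_epochs, function(e) c(e$start, e$end), numeric(2)))
    check_that(all(se[, 2] > se[, 1]) && all(se[, 1] >= 0) &&
                 all(se[, 2] <= duration_s),
               "epochs must be within the signal", "stim_epochs")
    o <- order(se[, 1])
    check_that(all(se[o, 1][-1] >= se[o, 2][-nrow(se)]),
               "epochs must not overlap", "stim_epochs")
    for (e in stim_epochs)
      check_that(e$pattern %in% c("none", "pace8", "scrambled",
                                  "random_freq"),
                 "unknown stimulation pattern", "stim_epochs")
  }
  check_that(all(ripple_times >= 0 & ripple_times <= duration_s),
             "ripple times must be within the signal", "ripple_times")
  structure(list(duration_s = duration_s, fs = fs,
                 theta_base_freq = theta_base_freq,
                 theta_speed_gain = theta_speed_gain,
                 theta_amp = theta_amp, noise_amp = noise_amp,
                 noise_exponent = noise_exponent, stim_epochs = stim_epochs,
                 ripple_times = ripple_times, ripple_freq = ripple_freq,
                 ripple_amp_sd = ripple_amp_sd,
                 ripple_env_sd = ripple_env_sd),
            class = "lfp_plan")
}

# 1/f^a Gaussian noise with unit SD, by spectral shaping of white noise.
one_over_f_noise <- function(n, exponent) {
  white <- rnorm(n)
  if (exponent == 0) return(white)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # two-sided frequency index
  X <- X * f^(-exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Simulate an LFP trace with known ground truth
#'
#' @param plan An [lfp_plan()].
#' @param speed Optional running-speed series (cm/s) at the behavior frame
#'   rate; it is linearly interpolated to `plan$fs` and drives the theta
#'   frequency as `theta_base_freq + theta_speed_gain * speed(t)`.
#' @param speed_frame_rate Frame rate of `speed`, Hz (default 30).
#' @param seed Integer RNG seed.
#' @return A list with `lfp` (an `lfp_signal`: `samples` uV, `fs`,
#'   `time_s`, `stim_epochs`) and `truth` (ripple times, per-epoch pattern
#'   and realized frequency, theta frequency series, seed).
#' @export
simulate_lfp <- function(plan, speed = NULL, speed_frame_rate = 30,
                         seed = 1) {
  check_that(inherits(plan, "lfp_plan"), "need an lfp_plan", "plan")
  set.seed(as.integer(seed))
  fs <- plan$fs
  n <- round(plan$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  if (is.null(speed)) {
    sp <- rep(0, n)
  } else {
    ts <- (seq_along(speed) - 1) / speed_frame_rate
    check_that(max(ts) >= plan$duration_s - 1.5 / speed_frame_rate,
               "speed series shorter than the LFP plan", "speed")
    sp <- stats::approx(ts, speed, xout = t, rule = 2)$y
  }

  inst_f <- plan$theta_base_freq + plan$theta_speed_gain * sp
  phase <- 2 * pi * cumsum(inst_f) / fs
  theta <- plan$theta_amp * sin(phase)

  epoch_truth <- list()
  for (e in plan$stim_epochs) {
    idx <- which(t >= e$start & t < e$end)
    realized_freq <- NA_real_
    if (e$pattern == "pace8") {
      realized_freq <- 8
      theta[idx] <- plan$theta_amp * sin(2 * pi * 8 * (t[idx] - e$start))
    } else if (e$pattern == "random_freq") {
      realized_freq <- runif(1, 4, 12)
      theta[idx] <- plan$theta_amp *
        sin(2 * pi * realized_freq * (t[idx] - e$start))
    } else if (e$pattern == "scrambled") {
      # variance-matched broadband replacement of the theta drive
      theta[idx] <- rnorm(length(idx), 0, plan$theta_amp / sqrt(2))
    }
    epoch_truth[[length(epoch_truth) + 1L]] <-
      list(start = e$start, end = e$end, pattern = e$pattern,
           frequency = realized_freq)
  }

  noise <- plan$noise_amp * one_over_f_noise(n, plan$noise_exponent)
  x <- theta + noise
  bg_sd <- max(stats::sd(x), 1e-12)

  for (rt in plan$ripple_times) {
    idx <- which(abs(t - rt) <= 4 * plan$ripple_env_sd)
    env <- exp(-(t[idx] - rt)^2 / (2 * plan$ripple_env_sd^2))
    x[idx] <- x[idx] + plan$ripple_amp_sd * bg_sd * env *
      sin(2 * pi * plan$ripple_freq * (t[idx] - rt))
  }

  lfp <- structure(list(samples = x, fs = fs, time_s = t,
                        stim_epochs = plan$stim_epochs,
                        channel = "synthetic"),
                   class = "lfp_signal")
  list(lfp = lfp,
       truth = list(ripple_times = plan$ripple_times,
                    epochs = epoch_truth, theta_freq = inst_f,
                    background_sd = bg_sd, seed = as.integer(seed)))
}
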