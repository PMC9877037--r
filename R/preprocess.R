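#' Instantaneous running speed from a tracked trajectory
#'
#' Speed is the frame-to-frame displacement over the frame interval
#' (\eqn{\Delta d / \Delta t}), Gaussian-smoothed with a short kernel to
#' suppress tracking artifacts. The first value is duplicated so the output
#' has one entry per frame.
#'
#' @param position Numeric vector (1D, cm) or two-column matrix (2D, cm).
#' @param time_s Strictly increasing frame timestamps, s.
#' @param smooth_sigma_s Gaussian smoothing sigma in seconds (default 0.033,
#'   i.e. 33 ms).
#' @return Numeric vector of speeds (cm/s), same length as `time_s`.
#' @export
compute_speed <- function(position, time_s, smooth_sigma_s = 0.033) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 1)
  check_that(nrow(pos) == length(time_s), "length mismatch", "position")
  check_that(length(time_s) >= 2, "need at least 2 frames", "time_s")
  dt <- diff(time_s)
  check_that(all(dt > 0), "timestamps must be strictly increasing", "time_s")
  step <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                          pos[-nrow(pos), , drop = FALSE])^2))
  v <- c(step[1] / dt[1], step / dt)
  sigma_frames <- smooth_sigma_s / mean(dt)
  if (sigma_frames > 0) v <- gaussian_smooth(v, sigma_frames)
  pmax(v, 0)
}

#' Locomotion mask
#'
#' @param speed Speed series, cm/s.
#' @param threshold_cm_s Threshold; > 2 cm/s is used in the open field and
#'   > 5 cm/s on the linear track.
#' @return Logical vector, `TRUE` where `speed > threshold_cm_s`.
#' @export
locomotion_mask <- function(speed, threshold_cm_s) {
  check_that(threshold_cm_s > 0, "must be > 0", "threshold_cm_s")
  speed > threshold_cm_s
}

#' Binarize calcium traces
#'
#' Each trace is zero-phase low-pass filtered to remove high-frequency
#' fluctuations, z-scored over the session, and a frame is scored active when
#' the normalized amplitude exceeds `z_threshold` standard deviations AND the
#' first-order derivative (first difference of the filtered trace, labeled by
#' the later sample) is positive — i.e. only the rising phase of a transient
#' counts as activity.
#'
#' @param traces Cell-by-frame numeric matrix of relative fluorescence.
#' @param frame_rate Sampling rate, Hz; must exceed twice `lowpass_hz`.
#' @param z_threshold Amplitude threshold in SD units (default 2).
#' @param lowpass_hz Low-pass cutoff, Hz (default 2; 4th-order Butterworth,
#'   applied forward and backward).
#' @return Integer matrix in `{0, 1}` of the same shape as `traces`. Constant
#'   traces (zero SD) come back all-inactive.
#' @export
binarize_traces <- function(traces, frame_rate, z_threshold = 2,
                            lowpass_hz = 2) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  check_that(frame_rate > 2 * lowpass_hz,
             "frame_rate must exceed twice the low-pass cutoff", "frame_rate")
  bf <- signal::butter(4, lowpass_hz / (frame_rate / 2), type = "low")
  out <- matrix(0L, nrow(traces), ncol(traces))
  for (i in seq_len(nrow(traces))) {
    tr <- traces[i, ]
    if (stats::sd(tr) == 0) next
    filt <- as.numeric(signal::filtfilt(bf, tr))
    z <- safe_zscore(filt)
    rising <- c(FALSE, diff(filt) > 0)
    out[i, ] <- as.integer(z > z_threshold & rising)
  }
  dimnames(out) <- dimnames(traces)
  out
}

#' Derive linear-track task variables from a trajectory
#'
#' Reconstructs the task structure implied by the end sensors: runs are
#' completed on entry into the far end zone (alternating ends), the tone
#' state advances on each completion within a `runs_per_reward`-run block, a
#' reward is delivered at the completion of each block, and elapsed time and
#' distance travelled are reset at the first frame after a reward where the
#' animal is more than `departure_cm` from the reward end. A run is scored as
#' an error when the animal loses more than `reversal_cm` of progress toward
#' its target end before arriving (a full return to the origin sensor always
#' qualifies); a trial is correct when none of its runs is an error.
#'
#' @param time_s Frame timestamps, s.
#' @param x_cm 1D position along the track, cm.
#' @param track_length Track length, cm.
#' @param runs_per_reward Runs per reward (default 4).
#' @param sensor_zone_cm Depth of the end detection zones, cm (default 5).
#' @param departure_cm Distance from the reward end defining the departure
#'   that resets the elapsed-time/distance clocks (default 5).
#' @param reversal_cm Progress (cm) beyond which a run counts as under way,
#'   so that a subsequent return into the origin sensor zone is scored as an
#'   error (default 25). Partial retreats that never re-enter the origin
#'   zone are not errors: only the end sensors can detect direction changes.
#' @param frame_rate Hz; inferred from `time_s` when `NULL`.
#' @return A `session_behavior` data frame; see [simulate_track_session()].
#' @export
derive_task_variables <- function(time_s, x_cm, track_length,
                                  runs_per_reward = 4, sensor_zone_cm = 5,
                                  departure_cm = 5, reversal_cm = 20,
                                  frame_rate = NULL) {
  n <- length(time_s)
  check_that(length(x_cm) == n, "length mismatch", "x_cm")
  check_that(all(x_cm >= -1e-6 & x_cm <= track_length + 1e-6),
             "position outside the track", "x_cm")
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(time_s))
  L <- track_length
  in_low <- x_cm <= sensor_zone_cm
  in_high <- x_cm >= L - sensor_zone_cm

  # end-sensor triggers: alternate ends, starting toward the high end
  target_high <- TRUE
  trig_frames <- integer(0)
  i <- 1L
  while (i <= n) {
    hit <- if (target_high) in_high[i] else in_low[i]
    if (hit) {
      trig_frames <- c(trig_frames, i)
      target_high <- !target_high
    }
    i <- i + 1L
  }
  n_runs <- length(trig_frames)

  run_id <- integer(n)
  run_error <- logical(max(n_runs, 1))
  tone_state <- integer(n)
  reward_frames <- integer(0)
  prev <- 1L
  for (r in seq_len(n_runs)) {
    fr <- trig_frames[r]
    idx <- prev:fr
    run_id[idx] <- r
    goes_high <- (r %% 2 == 1)
    progress <- if (goes_high) x_cm[idx] else L - x_cm[idx]
    # error = origin sensor re-triggered after the run got under way
    # (progress beyond reversal_cm); only the end sensors can detect a
    # direction change, so partial retreats are not scored
    run_error[r] <- any(cummax(progress) > reversal_cm &
                          progress <= sensor_zone_cm)
    within <- ((r - 1) %% runs_per_reward)  # completed runs in block before r
    tone_state[idx] <- within
    if (r %% runs_per_reward == 0) reward_frames <- c(reward_frames, fr)
    prev <- fr + 1L
  }
  if (n_runs > 0 && prev <= n) run_id[prev:n] <- n_runs  # tail after last run

  # departures from the reward site (low end) reset the trial clocks
  reset_frames <- integer(0)
  anchor <- c(1L, reward_frames)
  for (a in anchor) {
    j <- a
    while (j <= n && x_cm[j] <= departure_cm) j <- j + 1L
    if (j <= n) reset_frames <- c(reset_frames, j)
  }
  reset_frames <- sort(unique(reset_frames))

  step <- c(0, abs(diff(x_cm)))
  cum_d <- cumsum(step)
  elapsed_s <- numeric(n); distance_cm <- numeric(n); trial_id <- integer(n)
  if (length(reset_frames) == 0) reset_frames <- 1L
  bounds <- c(reset_frames, n + 1L)
  if (reset_frames[1] > 1) {
    idx <- 1:(reset_frames[1] - 1)
    elapsed_s[idx] <- 0; distance_cm[idx] <- 0; trial_id[idx] <- 0L
  }
  for (k in seq_along(reset_frames)) {
    idx <- bounds[k]:(bounds[k + 1] - 1L)
    elapsed_s[idx] <- time_s[idx] - time_s[idx[1]]
    distance_cm[idx] <- cum_d[idx] - cum_d[idx[1]]
    trial_id[idx] <- k
  }

  n_trials <- max(trial_id)
  trial_correct_tab <- rep(NA, n_trials)
  for (tr in seq_len(n_trials)) {
    runs_in <- unique(run_id[trial_id == tr])
    runs_in <- runs_in[runs_in > 0]
    complete <- length(runs_in) >= runs_per_reward
    trial_correct_tab[tr] <- if (complete) !any(run_error[runs_in]) else NA
  }

  speed <- compute_speed(x_cm, time_s)
  beh <- data.frame(
    time_s = time_s, x_cm = x_cm, speed_cm_s = speed,
    locomotion = locomotion_mask(speed, 5),
    tone_state = tone_state, run_id = run_id, trial_id = trial_id,
    trial_correct = ifelse(trial_id > 0,
                           trial_correct_tab[pmax(trial_id, 1)], NA),
    elapsed_s = elapsed_s, distance_cm = distance_cm,
    stim_on = FALSE
  )
  class(beh) <- c("session_behavior", "data.frame")
  attr(beh, "runs") <- data.frame(
    run_id = seq_len(n_runs),
    t_end = time_s[trig_frames],
    error = run_error[seq_len(n_runs)]
  )
  attr(beh, "rewards") <- time_s[reward_frames]
  attr(beh, "trials") <- data.frame(trial_id = seq_len(n_trials),
                                    correct = trial_correct_tab)
  attr(beh, "frame_rate") <- frame_rate
  attr(beh, "track_length") <- track_length
  beh
}
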