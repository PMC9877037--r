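#' Linear-track session configuration
#'
#' Parameters of the simulated sequential-tone linear track: a 134-cm track
#' with pyroelectric sensors at both ends, three tones advancing on successive
#' end crossings, and a water reward delivered at the starting end on
#' completion of every `runs_per_reward`-th run. Elapsed time and distance
#' travelled are referenced to the departure from the reward site, so a
#' four-run block is the natural "trial" unit.
#'
#' Beyond the nominal kinematics the generator models the behavioral
#' variability that makes position, elapsed time, and distance travelled
#' dissociable in real animals (the point of the paradigm): per-run speed
#' jitter, end pauses, turn-around jitter inside the sensor zone, short
#' mid-run hesitations (partial retreats that do not re-enter the origin
#' sensor zone, hence are not scored as errors), full mid-run reversals
#' (scored as errors), and speed-scaled tracking/micro-movement jitter that
#' inflates path length the way real pose-tracking trajectories do.
#'
#' @param track_length Track length in cm (default 134).
#' @param n_runs Maximum number of completed end-to-end runs to simulate.
#' @param max_duration_s Optional session time budget, s: no new run starts
#'   after it is exhausted (the run in progress completes). Use it to pin
#'   the session length when behavioral variability makes per-run duration
#'   stochastic.
#' @param runs_per_reward Runs per reward delivery (default 4).
#' @param mean_speed Mean running speed, cm/s.
#' @param speed_cv Coefficient of variation of per-leg speed (unitless).
#' @param trial_speed_cv SD of a log-normal per-trial speed factor
#'   (unitless) modeling arousal-state differences between trials: some
#'   trials are run fast throughout, others slowly, which spreads the
#'   distance-at-elapsed-time relation across trials.
#' @param pause_range Length-2 numeric, uniform range of end-pause durations, s.
#' @param error_rate Per-run probability of a full mid-run direction reversal
#'   (returns to the origin end; scored as an error).
#' @param frame_rate Sampling rate of the behavior stream, Hz (default 30).
#' @param sensor_zone_cm Depth of the end-sensor detection zones, cm.
#' @param turn_jitter_cm Uniform jitter of the turn-around point inside the
#'   sensor zone, cm.
#' @param hesitation_rate Expected number of short mid-run hesitations per
#'   run (Poisson).
#' @param hesitation_range Uniform range of hesitation retreat lengths, cm.
#' @param stop_rate Expected number of mid-run stops per run (Poisson);
#'   mice frequently pause mid-track, which advances elapsed time while
#'   position and distance are frozen.
#' @param stop_range Uniform range of mid-run stop durations, s.
#' @param sortie_rate Expected number of start-of-run sorties per run
#'   (Poisson): partial excursions out of the end zone and back before the
#'   animal commits to the run. Sorties return close to, but not into, the
#'   origin sensor zone, so the task scores them as part of the run, not as
#'   errors.
#' @param sortie_depth_cm Uniform range of sortie depths, cm.
#' @param path_noise_cm SD of the smooth tracking/micro-movement jitter added
#'   to the trajectory while the animal moves, cm.
#' @param reversal_cm Progress (cm) beyond which a run counts as under way
#'   for error scoring; see [derive_task_variables()].
#' @return An object of class `track_config` (a validated list).
#' @export
track_config <- function(track_length = 134, n_runs = 80,
                         max_duration_s = 900, runs_per_reward = 4,
                         mean_speed = 22, speed_cv = 0.4,
                         trial_speed_cv = 0.45,
                         pause_range = c(1, 6), error_rate = 0.2,
                         frame_rate = 30, sensor_zone_cm = 5,
                         turn_jitter_cm = 4, hesitation_rate = 1.5,
                         hesitation_range = c(5, 30), stop_rate = 2,
                         stop_range = c(1, 5), sortie_rate = 0.8,
                         sortie_depth_cm = c(15, 110), path_noise_cm = 0.5,
                         reversal_cm = 25) {
  cfg <- list(track_length = track_length, n_runs = n_runs,
              max_duration_s = max_duration_s,
              runs_per_reward = runs_per_reward, mean_speed = mean_speed,
              speed_cv = speed_cv, trial_speed_cv = trial_speed_cv,
              pause_range = pause_range,
              error_rate = error_rate, frame_rate = frame_rate,
              sensor_zone_cm = sensor_zone_cm, turn_jitter_cm = turn_jitter_cm,
              hesitation_rate = hesitation_rate,
              hesitation_range = hesitation_range, stop_rate = stop_rate,
              stop_range = stop_range, sortie_rate = sortie_rate,
              sortie_depth_cm = sortie_depth_cm,
              path_noise_cm = path_noise_cm, reversal_cm = reversal_cm)
  check_that(is.numeric(track_length) && track_length > 0,
             "must be > 0", "track_length")
  check_that(is.numeric(n_runs) && n_runs >= 1, "must be >= 1", "n_runs")
  check_that(is.null(max_duration_s) || max_duration_s > 0,
             "must be > 0", "max_duration_s")
  check_that(runs_per_reward >= 1, "must be >= 1", "runs_per_reward")
  check_that(mean_speed > 0, "must be > 0", "mean_speed")
  check_that(speed_cv >= 0, "must be >= 0", "speed_cv")
  check_that(trial_speed_cv >= 0, "must be >= 0", "trial_speed_cv")
  check_that(length(pause_range) == 2 && all(pause_range >= 0) &&
               pause_range[2] >= pause_range[1],
             "must be a non-negative increasing pair", "pause_range")
  check_that(error_rate >= 0 && error_rate < 1, "must be in [0, 1)",
             "error_rate")
  check_that(frame_rate > 0, "must be > 0", "frame_rate")
  check_that(sensor_zone_cm > 0 && sensor_zone_cm < track_length / 4,
             "must be positive and small relative to the track",
             "sensor_zone_cm")
  check_that(turn_jitter_cm >= 0 && turn_jitter_cm <= sensor_zone_cm,
             "must be within the sensor zone", "turn_jitter_cm")
  check_that(hesitation_rate >= 0, "must be >= 0", "hesitation_rate")
  check_that(all(hesitation_range > 0) &&
               hesitation_range[2] >= hesitation_range[1],
             "must be a positive increasing pair", "hesitation_range")
  check_that(sortie_rate >= 0, "must be >= 0", "sortie_rate")
  check_that(all(sortie_depth_cm > sensor_zone_cm) &&
               sortie_depth_cm[2] < track_length - sensor_zone_cm,
             "sortie depths must lie between the end zones",
             "sortie_depth_cm")
  check_that(stop_rate >= 0, "must be >= 0", "stop_rate")
  check_that(all(stop_range >= 0) && stop_range[2] >= stop_range[1],
             "must be a non-negative increasing pair", "stop_range")
  check_that(path_noise_cm >= 0, "must be >= 0", "path_noise_cm")
  structure(cfg, class = "track_config")
}

#' Simulate a sequential-tone linear-track session
#'
#' Builds a piecewise-constant-velocity trajectory over `cfg$n_runs`
#' end-to-end runs, adds speed-scaled tracking jitter, and derives all task
#' variables (tone state, trials, rewards, elapsed time and distance since
#' departure from the reward site, error flags) with
#' [derive_task_variables()], so the generator and the analysis share one
#' definition of the task structure.
#'
#' @param cfg A [track_config()].
#' @param seed Integer RNG seed; identical seed and config reproduce the
#'   session bit-identically.
#' @return A `session_behavior` data frame (one row per frame) with columns
#'   `time_s`, `x_cm`, `speed_cm_s`, `locomotion`, `tone_state`, `run_id`,
#'   `trial_id`, `trial_correct`, `elapsed_s`, `distance_cm`, `stim_on`, and
#'   attributes `runs` (per-run table), `rewards` (reward times),
#'   `frame_rate`, `track_length`, and `config`.
#' @export
simulate_track_session <- function(cfg, seed) {
  if (!inherits(cfg, "track_config")) cfg <- do.call(track_config, cfg)
  check_that(is.numeric(seed) && length(seed) == 1, "single integer", "seed")
  set.seed(as.integer(seed))
  L <- cfg$track_length
  zone <- cfg$sensor_zone_cm

  wt <- numeric(4096); wx <- numeric(4096); np <- 1L
  wt[1] <- 0; wx[1] <- 0
  cur_t <- 0; cur_x <- 0
  push <- function(t, x) {
    if (np + 1L > length(wt)) { wt <<- c(wt, numeric(length(wt)))
                                wx <<- c(wx, numeric(length(wx))) }
    np <<- np + 1L; wt[np] <<- t; wx[np] <<- x
  }
  add_leg <- function(to_x, v) {
    d <- abs(to_x - cur_x)
    if (d < 1e-9) return(invisible())
    cur_t <<- cur_t + d / v; cur_x <<- to_x
    push(cur_t, cur_x)
  }
  add_pause <- function(dur) {
    if (dur <= 0) return(invisible())
    cur_t <<- cur_t + dur
    push(cur_t, cur_x)
  }
  trial_factor <- 1
  draw_v <- function() cfg$mean_speed * trial_factor *
    max(0.25, rnorm(1, 1, cfg$speed_cv))

  for (r in seq_len(cfg$n_runs)) {
    if (!is.null(cfg$max_duration_s) && cur_t >= cfg$max_duration_s) break
    if ((r - 1) %% cfg$runs_per_reward == 0 && cfg$trial_speed_cv > 0)
      trial_factor <- min(max(exp(rnorm(1, 0, cfg$trial_speed_cv)), 0.55),
                          1.6)
    dir <- if (r %% 2 == 1) 1 else -1
    origin <- cur_x
    target <- if (dir > 0) L - runif(1, 0, cfg$turn_jitter_cm)
              else runif(1, 0, cfg$turn_jitter_cm)
    span <- abs(target - origin)
    # start-of-run sorties: out of the end zone and back, before committing
    for (so in seq_len(stats::rpois(1, cfg$sortie_rate))) {
      depth <- runif(1, cfg$sortie_depth_cm[1], cfg$sortie_depth_cm[2])
      add_leg(origin + dir * depth, draw_v())
      add_pause(runif(1, 0, 0.5))
      add_leg(origin + dir * runif(1, zone + 1, zone + 5), draw_v())
    }
    if (runif(1) < cfg$error_rate) {
      # full reversal: return into the origin sensor zone, then run again
      rev_at <- origin + dir * span * runif(1, 0.2, 0.8)
      back_to <- if (dir > 0) runif(1, 1, zone * 0.8)
                 else L - runif(1, 1, zone * 0.8)
      add_leg(rev_at, draw_v())
      add_pause(runif(1, 0, 1))
      add_leg(back_to, draw_v())
      add_pause(runif(1, 0, 1))
    }
    # mid-run hesitations (short retreats) and stops, at uniform points
    n_h <- stats::rpois(1, cfg$hesitation_rate)
    n_s <- stats::rpois(1, cfg$stop_rate)
    if (n_h + n_s > 0) {
      start_x <- cur_x
      ev <- data.frame(at = runif(n_h + n_s, 0.15, 0.9),
                       kind = rep(c("hes", "stop"), c(n_h, n_s)))
      ev <- ev[order(ev$at), ]
      for (j in seq_len(nrow(ev))) {
        hx <- start_x + (target - start_x) * ev$at[j]
        add_leg(hx, draw_v())
        if (ev$kind[j] == "hes") {
          dest <- hx - dir * runif(1, cfg$hesitation_range[1],
                                   cfg$hesitation_range[2])
          dest <- min(max(dest, zone + 2), L - zone - 2)  # out of end zones
          add_leg(dest, draw_v())
        } else {
          add_pause(runif(1, cfg$stop_range[1], cfg$stop_range[2]))
        }
      }
    }
    add_leg(target, draw_v())
    add_pause(runif(1, cfg$pause_range[1], cfg$pause_range[2]))
  }
  add_pause(2)

  wt <- wt[seq_len(np)]; wx <- wx[seq_len(np)]
  n <- floor(cur_t * cfg$frame_rate) + 1L
  time_s <- (seq_len(n) - 1L) / cfg$frame_rate
  x <- stats::approx(wt, wx, xout = time_s, rule = 2)$y

  if (cfg$path_noise_cm > 0) {
    # AR(1) micro-movement jitter, amplitude scaled down while (nearly) still
    dt <- 1 / cfg$frame_rate
    rho <- exp(-dt / 0.4)
    innov <- rnorm(n, 0, cfg$path_noise_cm * sqrt(1 - rho^2))
    jit <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    base_speed <- c(0, abs(diff(x)) / dt)
    scale <- pmin(1, base_speed / 10)
    scale[base_speed < 1] <- 0.1
    x <- pmin(L, pmax(0, x + jit * scale))
  }

  beh <- derive_task_variables(time_s, x, track_length = L,
                               runs_per_reward = cfg$runs_per_reward,
                               sensor_zone_cm = zone,
                               reversal_cm = cfg$reversal_cm,
                               frame_rate = cfg$frame_rate)
  attr(beh, "config") <- cfg
  attr(beh, "seed") <- as.integer(seed)
  beh
}
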