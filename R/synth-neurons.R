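#' Specification of a synthetic tuned neuron
#'
#' A cell's per-frame activation probability is
#' \deqn{p(t) = p_0 + (p_1 - p_0) \prod_c \exp\!\left(-\frac{(v_c(t) - \mu_c)^2}{2\sigma_c^2}\right)}
#' over its tuning components \eqn{c} (one for exclusive cells, several for
#' conjunctive cells, none for untuned cells), with baseline \eqn{p_0} and
#' in-field peak \eqn{p_1}.
#'
#' @param cell_class One of `"place"`, `"time"`, `"distance"`,
#'   `"conjunctive"`, `"untuned"`.
#' @param field_center Field center in the tuned variable's units (cm for
#'   place/distance, s for time). Ignored for untuned cells.
#' @param field_width Gaussian SD of the field, same units.
#' @param peak_prob Per-frame activation probability at the field center.
#' @param baseline_prob Off-field per-frame activation probability.
#' @param components For conjunctive cells, a list of
#'   `list(variable, center, width)` entries; for exclusive cells it is
#'   built from `cell_class`/`field_center`/`field_width`.
#' @return A `cell_spec` object.
#' @export
cell_spec <- function(cell_class, field_center = NA, field_width = NA,
                      peak_prob = 0.3, baseline_prob = 0.02,
                      components = NULL) {
  cell_class <- match.arg(cell_class,
                          c("place", "time", "distance", "conjunctive",
                            "untuned"))
  check_that(baseline_prob >= 0 && baseline_prob < peak_prob &&
               peak_prob <= 1,
             "need 0 <= baseline_prob < peak_prob <= 1", "peak_prob")
  if (cell_class == "untuned") {
    components <- list()
  } else if (cell_class == "conjunctive") {
    check_that(is.list(components) && length(components) >= 2,
               "conjunctive cells need >= 2 components", "components")
  } else {
    check_that(is.finite(field_center) && is.finite(field_width) &&
                 field_width > 0, "finite center and positive width",
               "field_center")
    variable <- switch(cell_class, place = "location", time = "time",
                       distance = "distance")
    components <- list(list(variable = variable, center = field_center,
                            width = field_width))
  }
  structure(list(cell_class = cell_class, peak_prob = peak_prob,
                 baseline_prob = baseline_prob, components = components),
            class = "cell_spec")
}

#' Build a mixed synthetic population
#'
#' Convenience constructor drawing field centers uniformly over each
#' variable's usable range (margins trimmed so fields fit).
#'
#' @param n_place,n_time,n_distance,n_conjunctive,n_untuned Cell counts.
#' @param peak_prob,baseline_prob Activation probabilities shared by all
#'   cells.
#' @param location_range,time_range,distance_range Variable ranges used to
#'   place the fields (cm, s, cm).
#' @param widths Named list of field SDs per variable (defaults: location
#'   8 cm, time 4 s, distance 20 cm).
#' @param seed Integer seed for the field-center draws.
#' @return List of [cell_spec()] objects with a `classes` attribute.
#' @export
make_population <- function(n_place = 50, n_time = 30, n_distance = 20,
                            n_conjunctive = 0, n_untuned = 50,
                            peak_prob = 0.3, baseline_prob = 0.02,
                            location_range = c(4, 130),
                            time_range = c(15, 45),
                            distance_range = c(164, 1100),
                            widths = list(location = 8, time = 4,
                                          distance = 20),
                            seed = 1) {
  set.seed(as.integer(seed))
  ranges <- list(location = location_range, time = time_range,
                 distance = distance_range)
  draw_center <- function(var) {
    r <- ranges[[var]]; w <- widths[[var]]
    runif(1, r[1] + w, r[2] - w)
  }
  specs <- list()
  for (v in c("place", "time", "distance")) {
    nn <- switch(v, place = n_place, time = n_time, distance = n_distance)
    var <- switch(v, place = "location", time = "time", distance = "distance")
    for (i in seq_len(nn))
      specs[[length(specs) + 1L]] <- cell_spec(v, draw_center(var),
                                               widths[[var]],
                                               peak_prob, baseline_prob)
  }
  for (i in seq_len(n_conjunctive)) {
    vars <- sample(c("location", "time", "distance"), 2)
    comps <- lapply(vars, function(var)
      list(variable = var, center = draw_center(var),
           width = widths[[var]] * 2))
    specs[[length(specs) + 1L]] <-
      cell_spec("conjunctive", peak_prob = peak_prob,
                baseline_prob = baseline_prob, components = comps)
  }
  for (i in seq_len(n_untuned))
    specs[[length(specs) + 1L]] <- cell_spec("untuned",
                                             peak_prob = peak_prob,
                                             baseline_prob = baseline_prob)
  attr(specs, "classes") <- vapply(specs, function(s) s$cell_class, "")
  specs
}

#' Simulate calcium traces for a population of tuned neurons
#'
#' Per-frame activations are drawn Bernoulli from each cell's tuning model
#' evaluated on the session's behavioral variables, convolved with a
#' single-exponential calcium kernel, and corrupted with Gaussian noise.
#'
#' @param behavior A `session_behavior` data frame (linear track: columns
#'   `x_cm`, `elapsed_s`, `distance_cm`; open field: `x_cm`, `y_cm`).
#' @param specs List of [cell_spec()] objects.
#' @param calcium_tau Decay time constant of the calcium kernel, s
#'   (default 0.5).
#' @param noise_sd SD of the additive Gaussian noise on the traces
#'   (default 0.05, in trace units where a single activation has unit
#'   amplitude).
#' @param seed Integer RNG seed.
#' @return A list with `neural` (list: `traces` cells-by-frames matrix,
#'   `frame_rate`) and `truth` (list: `classes`, `specs`, `activations`
#'   cells-by-frames 0/1 matrix, `seed`).
#' @export
simulate_neurons <- function(behavior, specs, calcium_tau = 0.5,
                             noise_sd = 0.05, seed = 1) {
  check_that(nrow(behavior) > 0, "empty behavior", "behavior")
  check_that(length(specs) > 0, "empty spec list", "specs")
  set.seed(as.integer(seed))
  fr <- attr(behavior, "frame_rate")
  if (is.null(fr)) fr <- 1 / stats::median(diff(behavior$time_s))
  n <- nrow(behavior)
  vars <- list(location = behavior$x_cm,
               time = behavior$elapsed_s,
               distance = behavior$distance_cm)
  if (!is.null(behavior$y_cm)) vars$location_y <- behavior$y_cm

  n_cells <- length(specs)
  act <- matrix(0L, n_cells, n)
  for (k in seq_len(n_cells)) {
    s <- specs[[k]]
    gain <- rep(1, n)
    for (comp in s$components) {
      v <- vars[[comp$variable]]
      check_that(!is.null(v), paste("unknown variable", comp$variable),
                 "specs")
      rng <- range(v, na.rm = TRUE)
      check_that(comp$center >= rng[1] - comp$width &&
                   comp$center <= rng[2] + comp$width,
                 sprintf("field center %.1f outside the range of '%s'",
                         comp$center, comp$variable), "specs")
      gain <- gain * exp(-(v - comp$center)^2 / (2 * comp$width^2))
    }
    if (length(s$components) == 0) gain <- 0
    p <- s$baseline_prob + (s$peak_prob - s$baseline_prob) * gain
    act[k, ] <- stats::rbinom(n, 1, p)
  }

  # single-exponential calcium kernel (no rise time); the recursive filter
  # y_t = a_t + e^{-dt/tau} y_{t-1} is exactly convolution with that kernel
  decay <- exp(-1 / (calcium_tau * fr))
  traces <- t(apply(act, 1, function(a)
    as.numeric(stats::filter(a, decay, method = "recursive"))))
  if (noise_sd > 0)
    traces <- traces + matrix(rnorm(n_cells * n, 0, noise_sd), n_cells, n)

  list(neural = list(traces = traces, frame_rate = fr),
       truth = list(classes = vapply(specs, function(s) s$cell_class, ""),
                    specs = specs, activations = act,
                    seed = as.integer(seed)))
}

#' Simulate open-field exploration
#'
#' A smooth bounded random walk at the imaging frame rate: an
#' Ornstein-Uhlenbeck velocity process gated by a two-state (rest/move)
#' Markov modulation so the speed distribution spans both rest (< 2 cm/s)
#' and locomotion, with reflective walls.
#'
#' @param arena_cm Width and height of the arena, cm (default 45 x 45).
#' @param duration_s Session duration, s.
#' @param seed Integer RNG seed.
#' @param frame_rate Hz (default 30).
#' @return A `session_behavior` data frame with `time_s`, `x_cm`, `y_cm`,
#'   `speed_cm_s`, `locomotion` (> 2 cm/s), `stim_on`.
#' @export
simulate_open_field <- function(arena_cm = c(45, 45), duration_s = 600,
                                seed = 1, frame_rate = 30) {
  check_that(all(arena_cm > 0) && length(arena_cm) == 2,
             "two positive dimensions", "arena_cm")
  check_that(duration_s > 0, "must be > 0", "duration_s")
  set.seed(as.integer(seed))
  n <- round(duration_s * frame_rate)
  dt <- 1 / frame_rate
  # rest/move gating: mean bout ~ 4 s move, ~ 2 s rest
  p_stop <- dt / 4; p_go <- dt / 2
  moving <- logical(n); moving[1] <- TRUE
  u <- runif(n)
  for (i in 2:n)
    moving[i] <- if (moving[i - 1]) u[i] > p_stop else u[i] < p_go
  rho <- exp(-dt / 0.7)
  sig <- 12 * sqrt(1 - rho^2)
  vx <- as.numeric(stats::filter(rnorm(n, 0, sig), rho,
                                 method = "recursive"))
  vy <- as.numeric(stats::filter(rnorm(n, 0, sig), rho,
                                 method = "recursive"))
  gate <- ifelse(moving, 1, 0.05)
  x <- numeric(n); y <- numeric(n)
  x[1] <- arena_cm[1] / 2; y[1] <- arena_cm[2] / 2
  for (i in 2:n) {
    x[i] <- x[i - 1] + vx[i] * gate[i] * dt
    y[i] <- y[i - 1] + vy[i] * gate[i] * dt
    if (x[i] < 0) { x[i] <- -x[i]; vx[i] <- -vx[i] }
    if (x[i] > arena_cm[1]) { x[i] <- 2 * arena_cm[1] - x[i]; vx[i] <- -vx[i] }
    if (y[i] < 0) { y[i] <- -y[i]; vy[i] <- -vy[i] }
    if (y[i] > arena_cm[2]) { y[i] <- 2 * arena_cm[2] - y[i]; vy[i] <- -vy[i] }
  }
  time_s <- (seq_len(n) - 1) * dt
  speed <- compute_speed(cbind(x, y), time_s)
  beh <- data.frame(time_s = time_s, x_cm = x, y_cm = y,
                    speed_cm_s = speed,
                    locomotion = locomotion_mask(speed, 2),
                    stim_on = FALSE)
  class(beh) <- c("session_behavior", "data.frame")
  attr(beh, "frame_rate") <- frame_rate
  attr(beh, "arena_cm") <- arena_cm
  beh
}
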