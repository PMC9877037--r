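#' Binning specification for a behavioral variable
#'
#' Defaults follow the study conventions: 3-cm bins for location, 1-s bins
#' for elapsed time, 3-cm bins for distance travelled, with tuning-curve
#' smoothing sigmas of 5, 10 and 15 bins respectively. The default time and
#' distance ranges (8-80 s, 134-1350 cm) are sized so a four-run trial with
#' realistic path overhead fits, and they start past the reset-adjacent
#' zone where elapsed time and distance are degenerate with position (just
#' after the trial clock resets, small elapsed time or path length pins the
#' animal near the reward end by continuity, so tuning there is not
#' identifiable). Frames falling outside a variable's range are excluded
#' from that variable's analysis only.
#'
#' @param variable `"location"`, `"time"` or `"distance"`.
#' @param bin_size Bin width (cm or s).
#' @param range Length-2 numeric range of the variable.
#' @param sigma_bins Gaussian smoothing sigma, in bins.
#' @return A `binning_spec` object.
#' @export
binning_spec <- function(variable = c("location", "time", "distance"),
                         bin_size = NULL, range = NULL, sigma_bins = NULL) {
  variable <- match.arg(variable)
  defaults <- list(
    location = list(bin_size = 3, range = c(0, 134), sigma_bins = 5),
    time     = list(bin_size = 1, range = c(8, 80),  sigma_bins = 10),
    distance = list(bin_size = 3, range = c(134, 1350), sigma_bins = 15))
  d <- defaults[[variable]]
  if (is.null(bin_size)) bin_size <- d$bin_size
  if (is.null(range)) range <- d$range
  if (is.null(sigma_bins)) sigma_bins <- d$sigma_bins
  check_that(bin_size > 0, "must be > 0", "bin_size")
  check_that(length(range) == 2 && range[2] > range[1],
             "need max > min", "range")
  check_that(sigma_bins >= 0, "must be >= 0", "sigma_bins")
  structure(list(variable = variable, bin_size = bin_size, range = range,
                 sigma_bins = sigma_bins,
                 n_bins = as.integer(ceiling((range[2] - range[1]) /
                                               bin_size))),
            class = "binning_spec")
}

#' Bin a behavioral variable
#'
#' @param values Numeric vector of the variable.
#' @param spec A [binning_spec()].
#' @return Integer bin indices in `1..spec$n_bins`; `NA` outside the range.
#' @export
bin_values <- function(values, spec) {
  b <- floor((values - spec$range[1]) / spec$bin_size) + 1L
  b[values < spec$range[1] | values > spec$range[2]] <- NA_integer_
  b[b > spec$n_bins] <- spec$n_bins  # value exactly at the upper edge
  as.integer(b)
}

#' Bin centers of a binning specification
#' @param spec A [binning_spec()].
#' @return Numeric vector of bin centers in the variable's units.
#' @export
bin_centers <- function(spec) {
  spec$range[1] + (seq_len(spec$n_bins) - 0.5) * spec$bin_size
}

#' Activity-likelihood tuning curve
#'
#' Estimates the probability of a cell being active given the binned state,
#' \eqn{P(A | S_i)} = (active frames in bin i) / (frames in bin i), plus the
#' marginal activity likelihood \eqn{P(A)}. Unoccupied bins are `NA` and are
#' excluded both from information measures and from the smoothing-kernel
#' normalization.
#'
#' @param activity Binary (0/1) activity vector, already restricted to the
#'   analyzed (e.g. locomotion) frames.
#' @param bins Integer bin indices aligned with `activity` (`NA` allowed and
#'   dropped together with the matching frames).
#' @param spec A [binning_spec()], or `NULL` with `n_bins`/`sigma_bins`
#'   given directly.
#' @param n_bins,sigma_bins Used when no `spec` is supplied.
#' @return A `tuning_curve` list: `likelihood`, `smoothed`, `occupancy`,
#'   `p_active`, `n_frames`, `spec`.
#' @export
compute_tuning_curve <- function(activity, bins, spec = NULL, n_bins = NULL,
                                 sigma_bins = 0) {
  if (!is.null(spec)) { n_bins <- spec$n_bins; sigma_bins <- spec$sigma_bins }
  ok <- !is.na(bins)
  activity <- activity[ok]; bins <- bins[ok]
  check_that(length(activity) > 0, "zero analyzed frames", "activity")
  occ <- tabulate(bins, n_bins)
  act <- tabulate(bins[activity == 1], n_bins)
  lik <- ifelse(occ > 0, act / occ, NA_real_)
  structure(list(likelihood = lik,
                 smoothed = gaussian_smooth(lik, sigma_bins),
                 occupancy = occ,
                 p_active = mean(activity),
                 n_frames = length(activity),
                 spec = spec),
            class = "tuning_curve")
}

# Mutual information (bits) between a binary activity variable and a binned
# state, from active counts per bin. `c1` may be an M x B matrix of counts
# for B surrogates; returns a length-B vector.
mi_from_counts <- function(c1, occ, n) {
  c1 <- as.matrix(c1)
  k <- colSums(c1)
  p_s <- occ / n
  term <- function(joint, p_a) {
    pa_mat <- matrix(p_a, nrow(joint), ncol(joint), byrow = TRUE)
    den <- p_s * pa_mat
    out <- joint * log2(joint / den)
    out[joint == 0] <- 0
    out
  }
  j1 <- c1 / n
  j0 <- (occ - c1) / n
  colSums(term(j1, k / n)) + colSums(term(j0, 1 - k / n))
}

#' Mutual information between binary activity and a binned state
#'
#' Plug-in estimate, in bits:
#' \deqn{MI = \sum_{i=1}^{M}\sum_{j\in\{0,1\}} P(S_i \cap A_j)
#'   \log_2 \frac{P(S_i \cap A_j)}{P(S_i) P(A_j)}}
#' Zero-probability cells contribute 0; the result is non-negative.
#'
#' @inheritParams compute_tuning_curve
#' @param n_bins Number of states; defaults to `max(bins)`.
#' @return MI in bits (scalar).
#' @export
compute_mi <- function(activity, bins, n_bins = NULL) {
  ok <- !is.na(bins)
  activity <- activity[ok]; bins <- bins[ok]
  if (length(activity) == 0) return(0)
  if (is.null(n_bins)) n_bins <- max(bins)
  occ <- tabulate(bins, n_bins)
  as.numeric(mi_from_counts(tabulate(bins[activity == 1], n_bins), occ,
                            length(activity)))
}

#' Circular-permutation significance test for tuning
#'
#' Generates surrogates by circularly shifting the binary activity vector by
#' random offsets (at least one second's worth of frames away from identity),
#' recomputing MI for each, and reporting the non-parametric p-value: the
#' number of surrogate MI values strictly greater than the actual MI, divided
#' by the number of permutations. Circular shifts preserve the burst
#' structure of calcium transients while breaking the alignment with
#' behavior, which makes the test conservative compared to frame-wise
#' randomization.
#'
#' @inheritParams compute_mi
#' @param n_shuffles Number of surrogates (default 1000, minimum 100).
#' @param seed Optional integer seed for the surrogate offsets.
#' @param frame_rate Frames per second of the series; sets the minimum
#'   shift (default 30, i.e. one second).
#' @details `activity` and `bins` span the whole session; frames excluded
#'   from the analysis (non-locomotion, out-of-range values) are marked by
#'   `NA` bins. Each surrogate rotates the *full-session* activity vector
#'   and then re-applies the exclusion mask, so that under the null
#'   (activity independent of behavior, circularly stationary) the actual
#'   series is exchangeable with its rotations and the p-value is exactly
#'   calibrated even when the mask is correlated with the behavioral
#'   variable.
#' @return List: `mi` (bits), `p` (p-value), `shuffle_mi` (surrogate MI
#'   values), `n_shuffles`. All-silent cells get `mi = 0`, `p = 1`.
#' @export
circular_shuffle_test <- function(activity, bins, n_bins = NULL,
                                  n_shuffles = 1000, seed = NULL,
                                  frame_rate = 30) {
  check_that(n_shuffles >= 100, "need at least 100 surrogates", "n_shuffles")
  check_that(length(activity) == length(bins), "length mismatch", "bins")
  if (!is.null(seed)) set.seed(as.integer(seed))
  activity <- as.integer(activity)
  n_full <- length(activity)
  ok <- !is.na(bins)
  n <- sum(ok)
  check_that(n > 0, "zero analyzed frames", "bins")
  if (is.null(n_bins)) n_bins <- max(bins, na.rm = TRUE)
  bins0 <- bins
  bins0[!ok] <- 0L  # excluded frames drop out of tabulate()
  bins0 <- as.integer(bins0)
  act_idx <- which(activity == 1L)
  k_full <- length(act_idx)
  if (k_full == 0 || all(activity[ok] == 1L)) {
    return(list(mi = 0, p = 1,
                shuffle_mi = rep(0, n_shuffles), n_shuffles = n_shuffles))
  }
  occ <- tabulate(bins0, n_bins)
  mi <- as.numeric(mi_from_counts(tabulate(bins0[act_idx], n_bins), occ, n))

  min_shift <- max(1L, min(round(frame_rate), floor((n_full - 1) / 2)))
  shifts <- sample(seq.int(min_shift, n_full - min_shift), n_shuffles,
                   replace = TRUE)
  # rotate the full-session activity, then mask: all surrogates at once
  sh <- (outer(act_idx - 1L, shifts, "+") %% n_full) + 1L
  bb <- matrix(bins0[sh], nrow = k_full)
  keep <- bb > 0L  # actives landing on excluded frames drop out
  idx <- bb + (rep(seq_len(n_shuffles), each = k_full) - 1L) * n_bins
  c1 <- matrix(tabulate(idx[keep], nbins = n_bins * n_shuffles),
               n_bins, n_shuffles)
  shuffle_mi <- mi_from_counts(c1, occ, n)
  list(mi = mi, p = sum(shuffle_mi > mi) / n_shuffles,
       shuffle_mi = shuffle_mi, n_shuffles = n_shuffles)
}

#' Classify cells from per-variable shuffle p-values
#'
#' A cell significant (p <= alpha) for exactly one variable is labeled with
#' that variable; significant for two or more, `"conjunctive"`; none,
#' `"none"`.
#'
#' @param p_values Cells-by-variables matrix (or length-3 vector) of
#'   shuffle p-values; column names name the variables.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of labels.
#' @export
classify_cells <- function(p_values, alpha = 0.05) {
  if (is.null(dim(p_values))) p_values <- matrix(p_values, nrow = 1,
    dimnames = list(NULL, names(p_values)))
  vars <- colnames(p_values)
  if (is.null(vars)) vars <- c("location", "time", "distance")[
    seq_len(ncol(p_values))]
  label_map <- c(location = "place", time = "time", distance = "distance")
  apply(p_values <= alpha, 1, function(sig) {
    if (sum(sig) == 0) "none"
    else if (sum(sig) == 1) {
      v <- vars[sig]
      if (v %in% names(label_map)) label_map[[v]] else v
    } else "conjunctive"
  })
}

#' Optogenetic stimulation modulation of a cell
#'
#' Treats the binarized stimulation signal as a two-state behavioral
#' variable, computes the MI between it and the cell's activity, and
#' assesses significance with the same circular-permutation test. The
#' direction is `"excited"` when P(active | stim) > P(active | no stim),
#' `"inhibited"` otherwise.
#'
#' @param activity Binary activity vector.
#' @param stim_mask Logical stimulation mask, same length; must contain both
#'   states.
#' @inheritParams circular_shuffle_test
#' @return List: `mi`, `p`, `direction` (`NA` for never-active cells),
#'   `p_active_stim`, `p_active_nostim`.
#' @export
stim_modulation <- function(activity, stim_mask, n_shuffles = 1000,
                            seed = NULL, frame_rate = 30) {
  check_that(length(stim_mask) == length(activity), "length mismatch",
             "stim_mask")
  check_that(any(stim_mask) && any(!stim_mask),
             "stimulation mask must contain both states", "stim_mask")
  bins <- as.integer(stim_mask) + 1L
  res <- circular_shuffle_test(activity, bins, n_bins = 2L,
                               n_shuffles = n_shuffles, seed = seed,
                               frame_rate = frame_rate)
  p1 <- mean(activity[stim_mask]); p0 <- mean(activity[!stim_mask])
  dir <- if (sum(activity) == 0) NA_character_
         else if (p1 > p0) "excited" else "inhibited"
  list(mi = res$mi, p = res$p, direction = dir,
       p_active_stim = p1, p_active_nostim = p0)
}

#' Two-dimensional activity-likelihood rate map
#'
#' Likelihood of activity per 2D spatial bin, Gaussian-smoothed by smoothing
#' the active-frame and occupancy count maps separately and dividing, so
#' unvisited bins do not dilute their neighbors. Bins never occupied are
#' `NA`.
#'
#' @param activity Binary activity vector.
#' @param x,y Position series, cm.
#' @param mask Logical frames-to-use mask (e.g. locomotion, epoch).
#' @param arena_cm Arena dimensions, cm.
#' @param bin_cm Spatial bin size, cm (default 3).
#' @param sigma_bins Gaussian smoothing sigma, bins (default 2).
#' @return List: `map` (smoothed likelihood matrix, x-by-y), `raw`,
#'   `occupancy`.
#' @export
rate_map_2d <- function(activity, x, y, mask = NULL, arena_cm = c(45, 45),
                        bin_cm = 3, sigma_bins = 2) {
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  check_that(any(mask), "empty epoch", "mask")
  a <- activity[mask]; xx <- x[mask]; yy <- y[mask]
  nx <- ceiling(arena_cm[1] / bin_cm); ny <- ceiling(arena_cm[2] / bin_cm)
  bx <- pmin(pmax(floor(xx / bin_cm) + 1L, 1L), nx)
  by <- pmin(pmax(floor(yy / bin_cm) + 1L, 1L), ny)
  idx <- (by - 1L) * nx + bx
  occ <- matrix(tabulate(idx, nx * ny), nx, ny)
  act <- matrix(tabulate(idx[a == 1], nx * ny), nx, ny)
  smooth2 <- function(m) {
    m <- apply(m, 2, gaussian_smooth, sigma = sigma_bins)
    t(apply(m, 1, gaussian_smooth, sigma = sigma_bins))
  }
  map <- smooth2(act) / smooth2(occ)
  map[smooth2(occ) == 0] <- NA_real_
  raw <- ifelse(occ > 0, act / occ, NA_real_)
  map[occ == 0 & !is.finite(map)] <- NA_real_
  list(map = map, raw = raw, occupancy = occ)
}

#' Field stability: correlation of two tuning curves
#'
#' Pearson correlation over jointly occupied (non-missing) bins of two
#' tuning curves or rate maps with identical binning.
#'
#' @param curve_a,curve_b Numeric vectors/matrices or `tuning_curve`
#'   objects (their smoothed curves are used).
#' @return Pearson r, or `NA` (with a warning) when either input is
#'   constant over the shared bins.
#' @export
field_stability <- function(curve_a, curve_b) {
  get_vals <- function(cv)
    if (inherits(cv, "tuning_curve")) cv$smoothed else as.numeric(cv)
  a <- get_vals(curve_a); b <- get_vals(curve_b)
  check_that(length(a) == length(b), "curves must share binning", "curve_b")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("field_stability undefined for constant or near-empty curves")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Classify every cell of a linear-track session
#'
#' Runs the tuning-curve / MI / circular-shuffle pipeline for location,
#' elapsed time, and distance travelled on locomotion frames, and labels
#' each cell with [classify_cells()].
#'
#' @param binary Cells-by-frames binary activity matrix.
#' @param behavior A `session_behavior` data frame for the same frames.
#' @param specs Named list of [binning_spec()]s (defaults for the three
#'   variables).
#' @param alpha Significance level (default 0.05).
#' @param n_shuffles Surrogates per test (default 1000).
#' @param seed Integer seed (one stream for all cells).
#' @param speed_threshold Locomotion threshold, cm/s (default 5, linear
#'   track).
#' @return Data frame with per-cell MI, p-value for each variable, and
#'   `label`; tuning curves in the `curves` attribute (list of
#'   variable -> cells-by-bins likelihood matrices).
#' @export
classify_session <- function(binary, behavior, specs = NULL, alpha = 0.05,
                             n_shuffles = 1000, seed = 1,
                             speed_threshold = 5) {
  if (is.null(specs))
    specs <- list(location = binning_spec("location"),
                  time = binning_spec("time"),
                  distance = binning_spec("distance"))
  set.seed(as.integer(seed))
  fr <- attr(behavior, "frame_rate")
  if (is.null(fr)) fr <- 1 / stats::median(diff(behavior$time_s))
  loco <- behavior$speed_cm_s > speed_threshold
  values <- list(location = behavior$x_cm, time = behavior$elapsed_s,
                 distance = behavior$distance_cm)
  n_cells <- nrow(binary)
  out <- data.frame(cell = seq_len(n_cells))
  curves <- list()
  pmat <- matrix(NA_real_, n_cells, length(specs),
                 dimnames = list(NULL, names(specs)))
  for (v in names(specs)) {
    sp <- specs[[v]]
    bins_full <- bin_values(values[[v]], sp)
    bins_full[!loco] <- NA_integer_
    cmat <- matrix(NA_real_, n_cells, sp$n_bins)
    mi_v <- numeric(n_cells); p_v <- numeric(n_cells)
    for (k in seq_len(n_cells)) {
      a <- binary[k, ]
      res <- circular_shuffle_test(a, bins_full, n_bins = sp$n_bins,
                                   n_shuffles = n_shuffles,
                                   frame_rate = fr)
      mi_v[k] <- res$mi; p_v[k] <- res$p
      cmat[k, ] <- compute_tuning_curve(a, bins_full, spec = sp)$smoothed
    }
    out[[paste0("mi_", v)]] <- mi_v
    out[[paste0("p_", v)]] <- p_v
    pmat[, v] <- p_v
    curves[[v]] <- cmat
  }
  out$label <- classify_cells(pmat, alpha = alpha)
  attr(out, "curves") <- curves
  attr(out, "alpha") <- alpha
  out
}
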