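#' Fit a naive Bayes decoder
#'
#' Estimates, per cell and state bin, the activity likelihood P(A_k | S_i)
#' from the training frames (occupancy-normalized active-frame counts), the
#' marginal activation rate P(A_k), and a uniform prior over the bins
#' occupied in training. Likelihoods are clipped to
#' `[1/(occupancy_i + 2), 1 - 1/(occupancy_i + 2)]` (add-one style) so a
#' cell silent in some bin cannot zero out the posterior.
#'
#' @param binary Cells-by-frames binary training matrix (locomotion frames).
#' @param bins Integer training-state bins aligned with the frames (`NA`
#'   frames are dropped).
#' @param spec A [binning_spec()] giving the bin count and centers.
#' @return A `decoder_model` list: `lik` (cells x bins, clipped), `prior`,
#'   `p_active`, `occupied`, `centers`, `spec`.
#' @export
fit_decoder <- function(binary, bins, spec) {
  if (is.vector(binary)) binary <- matrix(binary, nrow = 1)
  ok <- !is.na(bins)
  binary <- binary[, ok, drop = FALSE]; bins <- bins[ok]
  n <- length(bins)
  check_that(n > 0, "no training frames", "bins")
  m <- spec$n_bins
  occ <- tabulate(bins, m)
  occupied <- occ > 0
  # active counts per cell per bin in one pass
  ind <- matrix(0, n, m); ind[cbind(seq_len(n), bins)] <- 1
  act <- binary %*% ind                       # cells x bins
  lik <- sweep(act, 2, pmax(occ, 1), "/")
  floor_ <- matrix(1 / (pmax(occ, 1) + 2), nrow(binary), m, byrow = TRUE)
  lik <- pmin(pmax(lik, floor_), 1 - floor_)
  lik[, !occupied] <- NA_real_
  prior <- ifelse(occupied, 1 / sum(occupied), 0)
  structure(list(lik = lik, prior = prior,
                 p_active = rowMeans(binary),
                 occupied = occupied, occupancy = occ,
                 centers = bin_centers(spec), spec = spec,
                 n_train = n),
            class = "decoder_model")
}

#' Decode behavioral states from population activity
#'
#' Combines per-neuron evidence across cells and across a trailing temporal
#' window of `window_s` seconds. Two scoring variants are provided:
#'
#' * `"exact"` (default): the log-posterior
#'   \eqn{\sum_k \log P(A_k | S_i) + \log P(S_i)} using the full binary
#'   likelihood (active frames contribute \eqn{P(A_k{=}1|S)}, inactive
#'   frames the complement), summed over the trailing window, normalized
#'   per frame. This is Bayes' rule under the independence assumption.
#' * `"published"`: the scoring printed in the original analysis,
#'   \eqn{\sum_k \log(1 + P(A_k|S_i) P(S_i) / P(A_k)) - 1} with
#'   \eqn{A_k} the observed activity level of cell k (a monotone
#'   log(1+x) compression of the per-neuron posterior ratios).
#'
#' The decoded state is the maximum a posteriori bin; argmax ties break to
#' the lowest bin index. Frames with no finite evidence fall back to the
#' prior and are flagged.
#'
#' @param model A [fit_decoder()] model.
#' @param binary Cells-by-frames binary test matrix.
#' @param actual_bins Optional true bins for the test frames, to compute
#'   errors and a confusion matrix.
#' @param window_s Temporal filtering window, s (default 2; use 0 for
#'   single-frame decoding).
#' @param frame_rate Frames per second of the test series (default 30).
#' @param method `"exact"` or `"published"`.
#' @return A `decoding_result` list: `posterior` (bins x frames, columns sum
#'   to 1), `map_bin`, `map_value` (bin centers), `actual_bin`,
#'   `error` (|decoded - actual| in the variable's units), `mean_error`,
#'   `confusion` (row-normalized actual x decoded rates), `method`.
#' @export
decode <- function(model, binary, actual_bins = NULL, window_s = 2,
                   frame_rate = 30, method = c("exact", "published")) {
  method <- match.arg(method)
  if (is.vector(binary)) binary <- matrix(binary, nrow = 1)
  check_that(nrow(binary) == nrow(model$lik),
             "cell count differs from the fitted model", "binary")
  occ_idx <- which(model$occupied)
  lik <- model$lik[, occ_idx, drop = FALSE]
  prior <- model$prior[occ_idx]
  nf <- ncol(binary)

  if (method == "exact") {
    scores <- t(log(lik)) %*% binary +
      t(log1p(-lik)) %*% (1 - binary)          # occupied-bins x frames
    scores <- scores + log(prior)
  } else {
    # published scoring: log(1 + P(A_k|S) P(S) / P(A_k)) summed over cells,
    # with A_k the observed activity level of cell k (so inactive cells
    # contribute their complement likelihood), minus one
    pm <- matrix(prior, nrow(lik), length(prior), byrow = TRUE)
    e1 <- log1p(lik * pm / pmax(model$p_active, 1e-12))
    e0 <- log1p((1 - lik) * pm / pmax(1 - model$p_active, 1e-12))
    scores <- t(e1) %*% binary + t(e0) %*% (1 - binary) - 1
  }

  w <- max(1L, round(window_s * frame_rate))
  if (w > 1L) {
    # trailing-window sum of per-frame evidence (log space)
    cs <- cbind(0, t(apply(scores, 1, cumsum)))
    lead <- pmax(seq_len(nf) - w, 0L)
    scores <- cs[, seq_len(nf) + 1L, drop = FALSE] - cs[, lead + 1L,
                                                        drop = FALSE]
  }

  bad <- !apply(is.finite(scores), 2, any)
  if (any(bad)) scores[, bad] <- log(prior)
  mx <- apply(scores, 2, max)
  post <- exp(sweep(scores, 2, mx))
  post <- sweep(post, 2, colSums(post), "/")
  map_local <- apply(scores, 2, which.max)     # ties -> lowest index
  map_bin <- occ_idx[map_local]
  map_value <- model$centers[map_bin]

  err <- NULL; mean_err <- NA_real_; conf <- NULL; actual_value <- NULL
  if (!is.null(actual_bins)) {
    ok <- !is.na(actual_bins)
    actual_value <- model$centers[actual_bins]
    err <- abs(map_value - actual_value)
    mean_err <- mean(err[ok])
    conf <- confusion_matrix(actual_bins, map_bin,
                             n_bins = model$spec$n_bins)
  }
  structure(list(posterior = post, bins = occ_idx, map_bin = map_bin,
                 map_value = map_value, actual_bin = actual_bins,
                 actual_value = actual_value, error = err,
                 mean_error = mean_err, confusion = conf,
                 fallback_frames = which(bad), method = method),
            class = "decoding_result")
}

#' Row-normalized confusion matrix of actual versus decoded bins
#'
#' @param actual_bins,decoded_bins Aligned integer bin series.
#' @param n_bins Number of states.
#' @return n_bins x n_bins matrix of decoded-bin rates per actual bin; rows
#'   for unoccupied actual bins are `NA`.
#' @export
confusion_matrix <- function(actual_bins, decoded_bins, n_bins) {
  ok <- !is.na(actual_bins) & !is.na(decoded_bins)
  cm <- matrix(0, n_bins, n_bins)
  tab <- table(factor(actual_bins[ok], levels = seq_len(n_bins)),
               factor(decoded_bins[ok], levels = seq_len(n_bins)))
  cm[] <- as.numeric(tab)
  rs <- rowSums(cm)
  cm <- sweep(cm, 1, pmax(rs, 1), "/")
  cm[rs == 0, ] <- NA_real_
  cm
}

#' z-scored decoding error
#'
#' \eqn{z = (\bar{x} - \bar{s}) / \sigma(x)}, where \eqn{\bar{x}} is the
#' mean actual decoding error, \eqn{\bar{s}} the mean error of shuffled
#' surrogates, and \eqn{\sigma(x)} the SD of the actual errors. Negative z
#' means better-than-chance decoding; set `display_negated = TRUE` to report
#' the sign-flipped value ("higher is better").
#'
#' @param actual,shuffled Numeric error vectors (e.g. bootstrap means).
#' @param display_negated Flip the sign for display (default `FALSE`).
#' @return The z-score; `NA` with a warning when `sd(actual)` is zero.
#' @export
zscore_error <- function(actual, shuffled, display_negated = FALSE) {
  check_that(length(actual) > 0 && length(shuffled) > 0,
             "need non-empty error sets", "actual")
  s <- stats::sd(actual)
  if (!is.finite(s) || s == 0) {
    warning("zscore_error undefined: zero variance in actual errors")
    return(NA_real_)
  }
  z <- (mean(actual) - mean(shuffled)) / s
  if (display_negated) -z else z
}

#' Bootstrapped decoding error with shuffled surrogates
#'
#' Repeats `n_boot` times: sample `cells_per_boot` cells with replacement,
#' fit the decoder on the training split, decode the test split, and record
#' the mean error; a matched surrogate does the same after circularly
#' shifting each sampled cell's activity (breaking the behavior alignment
#' while preserving burst structure). The train/test split is contiguous:
#' the last `1 - train_frac` of the analyzed frames (trial-aligned when
#' `split_by` is given) is held out, preventing leakage through the calcium
#' autocorrelation.
#'
#' @param binary Cells-by-frames binary matrix (all frames).
#' @param values Behavioral variable series (same frames).
#' @param spec A [binning_spec()] for the decoded variable.
#' @param use Logical mask of analyzed frames (locomotion and in-range).
#' @param n_boot Number of bootstrap surrogates (default 50).
#' @param cells_per_boot Cells sampled with replacement per surrogate
#'   (default 160).
#' @param train_frac Fraction of analyzed frames used for training
#'   (default 0.9).
#' @param split_by Optional grouping vector (e.g. trial id); the holdout
#'   boundary is moved to the nearest group boundary.
#' @param window_s,frame_rate,method Passed to [decode()].
#' @param seed Integer seed.
#' @return List: `errors` (n_boot actual mean errors), `shuffled_errors`,
#'   `z` ([zscore_error()] of the two), `mean_error`,
#'   `mean_shuffled_error`, `n_test_frames`.
#' @export
bootstrap_decode <- function(binary, values, spec, use = NULL, n_boot = 50,
                             cells_per_boot = 160, train_frac = 0.9,
                             split_by = NULL, window_s = 2, frame_rate = 30,
                             method = "exact", seed = 1) {
  set.seed(as.integer(seed))
  bins_full <- bin_values(values, spec)
  if (is.null(use)) use <- rep(TRUE, length(values))
  use <- use & !is.na(bins_full)
  idx <- which(use)
  bins <- bins_full[idx]
  act <- binary[, idx, drop = FALSE]
  n <- length(idx)
  cut <- round(train_frac * n)
  if (!is.null(split_by)) {
    # hold out whole trials: back the boundary up to the start of the
    # group containing it, so the test split is never empty
    grp <- split_by[idx]
    while (cut > 1 && grp[cut + 1] == grp[cut]) cut <- cut - 1
    if (cut <= 1) cut <- round(train_frac * n)  # single-group fallback
  }
  train <- seq_len(cut); test <- seq.int(cut + 1L, n)
  check_that(length(test) > frame_rate, "test split too small", "train_frac")

  n_cells <- nrow(act)
  errors <- numeric(n_boot); sh_errors <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    cells <- sample.int(n_cells, cells_per_boot, replace = TRUE)
    ab <- act[cells, , drop = FALSE]
    fit <- fit_decoder(ab[, train, drop = FALSE], bins[train], spec)
    dec <- decode(fit, ab[, test, drop = FALSE], actual_bins = bins[test],
                  window_s = window_s, frame_rate = frame_rate,
                  method = method)
    errors[b] <- dec$mean_error
    # matched surrogate: per-cell circular shifts of the whole series
    shifts <- sample.int(n - 2L * frame_rate, cells_per_boot,
                         replace = TRUE) + frame_rate
    sh <- ab
    for (j in seq_len(cells_per_boot)) {
      s <- shifts[j]
      sh[j, ] <- ab[j, c((s + 1):n, 1:s)]
    }
    fit_s <- fit_decoder(sh[, train, drop = FALSE], bins[train], spec)
    dec_s <- decode(fit_s, sh[, test, drop = FALSE],
                    actual_bins = bins[test], window_s = window_s,
                    frame_rate = frame_rate, method = method)
    sh_errors[b] <- dec_s$mean_error
  }
  list(errors = errors, shuffled_errors = sh_errors,
       z = zscore_error(errors, sh_errors),
       mean_error = mean(errors), mean_shuffled_error = mean(sh_errors),
       n_test_frames = length(test))
}
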