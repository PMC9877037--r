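# Small helper: binning spec for a toy variable on [0, n) with unit bins
toy_spec <- function(n) binning_spec("location", bin_size = 1,
                                     range = c(0, n), sigma_bins = 0)

test_that("fitted likelihoods, priors and refits behave as defined", {
  # one-hot cells: cell k active exactly when in bin k
  bins <- rep(1:3, each = 40)
  binary <- rbind(as.integer(bins == 1), as.integer(bins == 2),
                  as.integer(bins == 3))
  m <- fit_decoder(binary, bins, toy_spec(3))
  # clipped to the add-one floor, not exactly 0/1
  expect_true(all(diag(m$lik) > 0.95))
  expect_true(all(m$lik[row(m$lik) != col(m$lik)] < 0.05))
  expect_equal(m$prior, rep(1 / 3, 3))
  m2 <- fit_decoder(binary, bins, toy_spec(3))
  expect_identical(m, m2)
  # uniform prior spreads over occupied bins only
  m3 <- fit_decoder(binary, bins, toy_spec(5))
  expect_equal(sum(m3$prior), 1)
  expect_equal(m3$prior[4:5], c(0, 0))
})

test_that("exact-variant posterior equals brute-force Bayes enumeration", {
  # 3 bins x 2 cells with hand-set likelihoods
  l1 <- c(0.9, 0.1, 0.1); l2 <- c(0.1, 0.1, 0.9)
  prior <- rep(1 / 3, 3)
  model <- structure(list(lik = rbind(l1, l2), prior = prior,
                          p_active = c(0.3, 0.3),
                          occupied = rep(TRUE, 3), occupancy = rep(100, 3),
                          centers = c(0.5, 1.5, 2.5), spec = toy_spec(3),
                          n_train = 300),
                     class = "decoder_model")
  obs <- matrix(c(1, 0), ncol = 1)  # cell 1 active, cell 2 inactive
  dec <- decode(model, obs, window_s = 0, method = "exact")
  brute <- prior * c(l1[1] * (1 - l2[1]), l1[2] * (1 - l2[2]),
                     l1[3] * (1 - l2[3]))
  brute <- brute / sum(brute)
  expect_equal(as.numeric(dec$posterior), brute, tolerance = 1e-10)
  expect_equal(dec$map_bin, which.max(brute))
})

test_that("posterior columns sum to one and silent frames fall back to prior", {
  bins <- rep(1:4, each = 30)
  set.seed(1)
  binary <- matrix(rbinom(5 * 120, 1, 0.2), nrow = 5)
  m <- fit_decoder(binary, bins, toy_spec(4))
  dec <- decode(m, matrix(0L, 5, 7), window_s = 0)
  expect_equal(colSums(dec$posterior), rep(1, 7))
  # all-silent frames: every bin carries the same evidence; tie -> lowest
  dec_pub <- decode(m, matrix(0L, 5, 3), window_s = 0, method = "published")
  expect_equal(colSums(dec_pub$posterior), rep(1, 3))
  expect_true(all(dec_pub$map_bin == 1))
})

test_that("decoding error is measured in the variable's units", {
  sp <- binning_spec("location", bin_size = 10, range = c(0, 30),
                     sigma_bins = 0)
  bins <- rep(1:3, each = 50)
  binary <- rbind(as.integer(bins == 1), as.integer(bins == 2),
                  as.integer(bins == 3))
  m <- fit_decoder(binary, bins, sp)
  dec <- decode(m, cbind(c(1, 0, 0)), actual_bins = 3L, window_s = 0)
  expect_equal(dec$map_value, 5)          # center of bin 1
  expect_equal(dec$error, 20)             # |5 - 25| cm
})

test_that("confusion matrices are row-normalized with missing rows flagged", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 1, 2, 2), n_bins = 3)
  expect_equal(diag(cm)[1:2], c(1, 1))
  expect_true(all(is.na(cm[3, ])))
  set.seed(2)
  act <- sample(1:5, 4000, replace = TRUE)
  decd <- sample(1:5, 4000, replace = TRUE)
  cm2 <- confusion_matrix(act, decd, n_bins = 5)
  expect_equal(rowSums(cm2), rep(1, 5))
  expect_true(all(abs(cm2 - 0.2) < 0.06))
})

test_that("error z-score follows the defined arithmetic", {
  expect_equal(zscore_error(c(1, 3), rep(5, 10)),
               (2 - 5) / sd(c(1, 3)))
  expect_equal(zscore_error(c(1, 3), rep(5, 10)), -2.12, tolerance = 0.01)
  expect_equal(zscore_error(c(2, 4), c(2, 4)), 0)
  expect_equal(zscore_error(c(1, 3), rep(5, 10), display_negated = TRUE),
               2.12, tolerance = 0.01)
  expect_warning(z <- zscore_error(rep(2, 5), c(1, 2)), "zero variance")
  expect_true(is.na(z))
})

test_that("temporal filtering reduces error on slow trajectories", {
  # slow ramp across bins with noisy one-hot-ish cells
  set.seed(3)
  n <- 3000
  true_bin <- pmin(10L, pmax(1L, as.integer(ceiling(
    10 * (1 + sin(seq(0, 6 * pi, length.out = n))) / 2 + 0.001))))
  binary <- t(vapply(1:10, function(k)
    rbinom(n, 1, ifelse(true_bin == k, 0.25, 0.02)), numeric(n)))
  sp <- toy_spec(10)
  train <- 1:2400; test <- 2401:n
  m <- fit_decoder(binary[, train], true_bin[train], sp)
  d1 <- decode(m, binary[, test], actual_bins = true_bin[test],
               window_s = 0, frame_rate = 30)
  d2 <- decode(m, binary[, test], actual_bins = true_bin[test],
               window_s = 2, frame_rate = 30)
  expect_lt(d2$mean_error, d1$mean_error)
})

test_that("published and exact scorings are interchangeable decoders", {
  # the log(1+x) compression shifts flat-topped score profiles by a bin or
  # two once evidence accumulates, so the variants are compared on what
  # they guarantee: near-identical single-frame choices and equivalent
  # decoding error under temporal filtering
  beh <- small_track()
  specs <- make_population(n_place = 20, n_time = 0, n_distance = 0,
                           n_untuned = 5, seed = 21)
  sim <- simulate_neurons(beh, specs, seed = 22)
  b <- binarize_traces(sim$neural$traces, 30)
  sp <- binning_spec("location")
  bins <- bin_values(beh$x_cm, sp)
  use <- beh$speed_cm_s > 5 & !is.na(bins)
  n <- sum(use); tr <- seq_len(round(0.9 * n)); te <- setdiff(seq_len(n), tr)
  bb <- b[, use]; bn <- bins[use]
  m <- fit_decoder(bb[, tr], bn[tr], sp)
  d0e <- decode(m, bb[, te], actual_bins = bn[te], window_s = 0,
                method = "exact")
  d0p <- decode(m, bb[, te], actual_bins = bn[te], window_s = 0,
                method = "published")
  expect_gt(mean(d0e$map_bin == d0p$map_bin), 0.85)
  d2e <- decode(m, bb[, te], actual_bins = bn[te], window_s = 2,
                frame_rate = 30, method = "exact")
  d2p <- decode(m, bb[, te], actual_bins = bn[te], window_s = 2,
                frame_rate = 30, method = "published")
  expect_lt(abs(d2e$mean_error - d2p$mean_error), 3)  # within one bin
})

test_that("bootstrap decoding separates tuned populations from chance", {
  beh <- small_track()
  specs <- make_population(n_place = 30, n_time = 0, n_distance = 0,
                           n_untuned = 5, seed = 31)
  sim <- simulate_neurons(beh, specs, seed = 32)
  b <- binarize_traces(sim$neural$traces, 30)
  res <- bootstrap_decode(b, beh$x_cm, binning_spec("location"),
                          use = beh$speed_cm_s > 5, n_boot = 10,
                          cells_per_boot = 60, split_by = beh$trial_id,
                          frame_rate = 30, seed = 33)
  expect_length(res$errors, 10)
  expect_true(all(res$errors < res$shuffled_errors))
  expect_lt(res$z, -2)
  # error is non-increasing in population size on average
  res_small <- bootstrap_decode(b[1:8, ], beh$x_cm,
                                binning_spec("location"),
                                use = beh$speed_cm_s > 5, n_boot = 10,
                                cells_per_boot = 8,
                                split_by = beh$trial_id, frame_rate = 30,
                                seed = 34)
  expect_lt(res$mean_error, res_small$mean_error)
})
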