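test_that("tuning curve is the occupancy-normalized activity likelihood", {
  bins <- rep(1:10, each = 20)
  act <- integer(200)
  act[bins == 7] <- 1L
  tc <- compute_tuning_curve(act, bins, n_bins = 10)
  expect_equal(tc$likelihood[7], 1)
  expect_equal(tc$likelihood[-7], rep(0, 9))
  expect_equal(sum(tc$occupancy), 200)
  # unoccupied bin is missing and excluded
  tc2 <- compute_tuning_curve(act, bins, n_bins = 12)
  expect_true(all(is.na(tc2$likelihood[11:12])))
  expect_error(compute_tuning_curve(integer(0), integer(0), n_bins = 2),
               "zero analyzed")
})

test_that("state-independent cells have flat tuning curves", {
  set.seed(1)
  bins <- sample(1:5, 5000, replace = TRUE)
  act <- rbinom(5000, 1, 0.2)
  tc <- compute_tuning_curve(act, bins, n_bins = 5)
  ci <- 3 * sqrt(0.2 * 0.8 / 1000)
  expect_true(all(abs(tc$likelihood - 0.2) < ci))
})

test_that("MI matches closed-form entropy arithmetic", {
  d <- two_state_data(n_per_state = 1000, p1 = 0.8, p2 = 0.2)
  # P(A)=0.5; MI = H(A) - H(A|S) = 1 - H(0.8)
  expect_equal(compute_mi(d$activity, d$bins), 1 - binary_entropy(0.8),
               tolerance = 1e-9)
  # deterministic dependence on a fair binary state: 1 bit
  ind <- two_state_data(n_per_state = 100, p1 = 1, p2 = 0)
  expect_equal(compute_mi(ind$activity, ind$bins), 1)
})

test_that("MI is non-negative and vanishes for independent data", {
  set.seed(2)
  mis <- replicate(20, {
    bins <- sample(1:8, 4000, replace = TRUE)
    compute_mi(rbinom(4000, 1, 0.1), bins)
  })
  expect_true(all(mis >= 0))
  expect_lt(mean(mis), 0.01)  # plug-in bias only
})

test_that("merging adjacent bins never increases MI", {
  set.seed(3)
  for (rep in 1:10) {
    bins <- sample(1:8, 2000, replace = TRUE)
    p <- runif(8)
    act <- rbinom(2000, 1, p[bins])
    merged <- (bins + 1L) %/% 2L
    expect_lte(compute_mi(act, merged, n_bins = 4),
               compute_mi(act, bins, n_bins = 8) + 1e-12)
  }
})

test_that("circular shuffle test: perfect tuning gives p = 0, seeds fix p", {
  set.seed(4)
  bins <- rep(rep(1:2, each = 25), 40)  # alternating state blocks
  act <- as.integer(bins == 1)
  r <- circular_shuffle_test(act, bins, n_bins = 2, n_shuffles = 200,
                             seed = 9, frame_rate = 10)
  expect_equal(r$p, 0)
  r2 <- circular_shuffle_test(act, bins, n_bins = 2, n_shuffles = 200,
                              seed = 9, frame_rate = 10)
  expect_identical(r$p, r2$p)
  expect_identical(r$shuffle_mi, r2$shuffle_mi)
  # all-silent cell: no information possible
  r3 <- circular_shuffle_test(integer(2000), bins, n_bins = 2,
                              n_shuffles = 100)
  expect_equal(r3$p, 1)
  expect_equal(r3$mi, 0)
})

test_that("classification follows the exclusive/conjunctive rule", {
  p <- rbind(c(0.01, 0.40, 0.30),
             c(0.01, 0.02, 0.90),
             c(0.20, 0.90, 0.80),
             c(0.90, 0.04, 0.30),
             c(0.90, 0.60, 0.05))
  colnames(p) <- c("location", "time", "distance")
  expect_equal(unname(classify_cells(p)),
               c("place", "conjunctive", "none", "time", "distance"))
  # boundary: p exactly alpha counts as significant
  expect_equal(unname(classify_cells(c(location = 0.05, time = 0.5,
                                       distance = 0.5))), "place")
})

test_that("stimulation modulation flags excited cells and degenerate cases", {
  set.seed(5)
  stim <- rep(rep(c(TRUE, FALSE), each = 150), 30)  # 5 s on / 5 s off @30Hz
  act <- rbinom(length(stim), 1, ifelse(stim, 0.4, 0.05))
  r <- stim_modulation(act, stim, n_shuffles = 300, seed = 6)
  expect_lte(r$p, 0.05)
  expect_equal(r$direction, "excited")
  r2 <- stim_modulation(integer(length(stim)), stim, n_shuffles = 100)
  expect_equal(r2$p, 1)
  expect_true(is.na(r2$direction))
  expect_error(stim_modulation(act, rep(TRUE, length(act))), "both states")
})

test_that("2D rate maps recover field centers and mark unvisited bins", {
  beh <- simulate_open_field(c(45, 45), duration_s = 900, seed = 11)
  center <- c(30, 15)
  gain <- exp(-((beh$x_cm - center[1])^2 + (beh$y_cm - center[2])^2) /
                (2 * 5^2))
  set.seed(12)
  act <- rbinom(nrow(beh), 1, 0.02 + 0.5 * gain)
  rm_ <- rate_map_2d(act, beh$x_cm, beh$y_cm, mask = beh$locomotion,
                     arena_cm = c(45, 45), bin_cm = 3)
  peak <- which(rm_$map == max(rm_$map, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lt(abs(peak[1] * 3 - 1.5 - center[1]), 4.6)  # within ~1.5 bins
  expect_lt(abs(peak[2] * 3 - 1.5 - center[2]), 4.6)
  expect_true(all(is.na(rm_$raw[rm_$occupancy == 0])))
  # untuned cell: map flat within binomial tolerance
  act0 <- rbinom(nrow(beh), 1, 0.1)
  rm0 <- rate_map_2d(act0, beh$x_cm, beh$y_cm, mask = beh$locomotion)
  vals <- rm0$map[rm0$occupancy > 50]
  expect_lt(diff(range(vals)), 0.25)
  expect_error(rate_map_2d(act0, beh$x_cm, beh$y_cm,
                           mask = rep(FALSE, nrow(beh))), "empty")
})

test_that("field stability is a Pearson correlation over shared bins", {
  a <- c(0.1, 0.5, 0.9, 0.4, 0.2)
  expect_equal(field_stability(a, a), 1)
  expect_equal(field_stability(a, 2 * mean(a) - a), -1)
  expect_warning(r <- field_stability(rep(1, 5), a), "constant")
  expect_true(is.na(r))
  set.seed(13)
  rs <- replicate(1000, field_stability(runif(45), runif(45)))
  expect_lt(abs(mean(rs)), 0.02)
})
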