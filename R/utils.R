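#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom fft sd cor approx filter quantile median
#' @importFrom utils head tail read.table write.table
NULL

# Validation helper: stop with the offending argument named.
check_that <- function(cond, msg, field = NULL) {
  if (!isTRUE(cond)) {
    if (!is.null(field)) msg <- sprintf("invalid '%s': %s", field, msg)
    stop(msg, call. = FALSE)
  }
  invisible(TRUE)
}

# Gaussian kernel (normalized), sigma and half-width in samples.
gaussian_kernel <- function(sigma, half_width = ceiling(4 * sigma)) {
  if (sigma <= 0) return(1)
  x <- seq(-half_width, half_width)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# NA-aware Gaussian smoothing of a vector; missing entries are excluded
# from the kernel normalization and stay missing in the output.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel(sigma)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  num <- as.numeric(stats::filter(c(rep(0, length(k)), x0, rep(0, length(k))),
                                  k, sides = 2))
  den <- as.numeric(stats::filter(c(rep(0, length(k)), as.numeric(ok),
                                    rep(0, length(k))), k, sides = 2))
  sm <- (num / den)[(length(k) + 1):(length(k) + length(x))]
  sm[!ok] <- NA_real_
  sm
}

# z-score that maps constant input to all zeros instead of NaN.
safe_zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Analytic signal via the frequency-domain construction (one-sided spectrum
# doubled); used for instantaneous amplitude/phase. No installed package
# exports a Hilbert transform, and the construction is a few lines.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase Butterworth band/low/high-pass. Bands far below Nyquist are
# filtered on a decimated copy and interpolated back: transfer-function
# Butterworth coefficients are numerically unstable at normalized cutoffs
# of ~1e-3 (the filtered signal diverges on long inputs).
butter_filtfilt <- function(x, fs, low = NULL, high = NULL, order = 4) {
  nyq <- fs / 2
  if (!is.null(low) && !is.null(high) && high < fs / 50) {
    k <- max(2L, floor(fs / (high * 12.5)))
    anti <- signal::butter(4, 0.8 / k, type = "low")
    xs <- as.numeric(signal::filtfilt(anti, x))[seq(1, length(x), by = k)]
    ys <- butter_filtfilt(xs, fs / k, low = low, high = high, order = order)
    t_full <- seq_along(x)
    return(stats::approx(t_full[seq(1, length(x), by = k)], ys,
                         xout = t_full, rule = 2)$y)
  }
  if (!is.null(low) && !is.null(high)) {
    check_that(high < nyq, "band edge above Nyquist", "high")
    bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  } else if (!is.null(high)) {
    check_that(high < nyq, "cutoff above Nyquist", "high")
    bf <- signal::butter(order, high / nyq, type = "low")
  } else {
    bf <- signal::butter(order, low / nyq, type = "high")
  }
  as.numeric(signal::filtfilt(bf, x))
}

# Draw a derived RNG seed (kept below 2^31) for sub-generators.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}
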