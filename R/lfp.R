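#' Canonical frequency bands
#'
#' The six named bands used throughout the LFP analyses: delta 1-4 Hz,
#' theta 4-12 Hz, alpha/beta 12-30 Hz, slow gamma 30-60 Hz, fast gamma
#' 60-120 Hz, HFO 120-250 Hz.
#'
#' @return Named list of length-2 numeric ranges (Hz).
#' @export
frequency_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 12), alpha_beta = c(12, 30),
       gamma_slow = c(30, 60), gamma_fast = c(60, 120), hfo = c(120, 250))
}

#' Complex Morlet wavelet spectrogram
#'
#' Convolves the signal with complex Morlet atoms (bandwidth parameter 1,
#' center frequency 1.5 — the 'cmor1-1.5' convention) at the requested
#' frequencies, via FFT. Power is the squared magnitude of the convolution;
#' atoms are L1-normalized so a unit-amplitude sinusoid yields comparable
#' ridge power at every frequency.
#'
#' @param x Signal (uV).
#' @param fs Sampling rate, Hz.
#' @param freqs Analysis frequencies, Hz (all below Nyquist).
#' @param bandwidth,center_freq Morlet parameters (defaults 1 and 1.5).
#' @return List: `power` (frequencies x time), `freqs`, `time_s`.
#' @export
wavelet_spectrogram <- function(x, fs, freqs, bandwidth = 1,
                                center_freq = 1.5) {
  check_that(all(freqs > 0 & freqs < fs / 2), "frequencies must be below
             Nyquist", "freqs")
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  power <- matrix(NA_real_, length(freqs), n)
  for (i in seq_along(freqs)) {
    scale <- center_freq / freqs[i]          # seconds per unit wavelet time
    half <- ceiling(4 * sqrt(bandwidth / 2) * scale * fs)
    tt <- (-half:half) / (fs * scale)        # wavelet time axis
    psi <- exp(-tt^2 / bandwidth) * exp(2i * pi * center_freq * tt)
    psi <- psi / sum(Mod(psi))
    kf <- stats::fft(c(psi, rep(0, nfft - length(psi))))
    conv <- stats::fft(X * kf, inverse = TRUE)[seq_len(n + half)] / nfft
    power[i, ] <- Mod(conv[(half + 1):(half + n)])^2
  }
  list(power = power, freqs = freqs, time_s = (seq_len(n) - 1) / fs)
}

# Shared moving-window Fourier machinery. Returns power (freqs x windows)
# using a 4-term Blackman-Harris taper; window/step in seconds.
movingwin_fft <- function(x, fs, window_s, step_s) {
  w <- round(window_s * fs)
  check_that(w <= length(x), "window longer than the signal", "window_s")
  s <- max(1L, round(step_s * fs))
  starts <- seq.int(1L, length(x) - w + 1L, by = s)
  nn <- 2 * pi * (0:(w - 1)) / (w - 1)
  taper <- 0.35875 - 0.48829 * cos(nn) + 0.14128 * cos(2 * nn) -
    0.01168 * cos(3 * nn)
  nf <- w %/% 2 + 1L
  P <- vapply(starts, function(st)
    Mod(stats::fft(x[st:(st + w - 1L)] * taper))[seq_len(nf)]^2,
    numeric(nf))
  if (is.null(dim(P))) P <- matrix(P, ncol = 1)
  list(power = P, freqs = (seq_len(nf) - 1L) * fs / w,
       times = (starts - 1L + w / 2) / fs)
}

#' Moving-window Fourier spectrum
#'
#' Tapered short-time Fourier power on sliding windows (2-s windows for the
#' theta band, 5-s windows for gamma, 10-ms steps by convention), with the
#' dominant in-band frequency per step.
#'
#' @param x Signal (uV).
#' @param fs Sampling rate, Hz.
#' @param band Length-2 frequency band of interest, Hz (default theta,
#'   4-12).
#' @param window_s Window length, s (default 2).
#' @param step_s Step between windows, s (default 0.01).
#' @return List: `power` (in-band frequencies x steps), `freqs` (in-band),
#'   `times` (window centers, s), `dominant_freq` (argmax per step, Hz).
#' @export
movingwin_spectrum <- function(x, fs, band = c(4, 12), window_s = 2,
                               step_s = 0.01) {
  mw <- movingwin_fft(x, fs, window_s, step_s)
  inb <- mw$freqs >= band[1] & mw$freqs <= band[2]
  P <- mw$power[inb, , drop = FALSE]
  f <- mw$freqs[inb]
  list(power = P, freqs = f, times = mw$times,
       dominant_freq = f[apply(P, 2, which.max)])
}

#' Oscillation strength
#'
#' The fraction of theta-band spectral power concentrated within +/- 1 Hz of
#' the band's peak oscillation frequency: 1 when all power sits at one
#' frequency (e.g. during 8 Hz pacing), ~ 0.5 for white noise. Estimated
#' with the theta-band moving-window convention (2-s tapered windows, 10-ms
#' steps); the peak frequency is tracked per window and the ratio taken on
#' power accumulated across windows, which reproduces both analytic
#' anchors (pure sinusoid = 1, white noise = 0.5).
#'
#' @param x Epoch signal (uV), at least 5 s long.
#' @param fs Sampling rate, Hz.
#' @param theta_band Band of interest, Hz (default 4-12).
#' @param halfwidth Half-width around the peak, Hz (default 1).
#' @param window_s,step_s Moving-window parameters (defaults 2 s, 10 ms).
#' @return Scalar OS in [0, 1], with the accumulated-power peak frequency as
#'   the `"peak_freq"` attribute.
#' @export
oscillation_strength <- function(x, fs, theta_band = c(4, 12),
                                 halfwidth = 1, window_s = 2,
                                 step_s = 0.01) {
  check_that(length(x) >= 5 * fs - 1, "epoch shorter than 5 s", "x")
  mw <- movingwin_fft(x, fs, window_s, step_s)
  inb <- mw$freqs >= theta_band[1] & mw$freqs <= theta_band[2]
  P <- mw$power[inb, , drop = FALSE]
  f <- mw$freqs[inb]
  peak_per_win <- f[apply(P, 2, which.max)]
  sel <- abs(outer(f, peak_per_win, "-")) <= halfwidth
  os <- sum(P[sel]) / sum(P)
  psd <- rowMeans(P)
  structure(os, peak_freq = f[which.max(psd)])
}

#' Band power portions of baseline
#'
#' Mean band power during stimulation epochs divided by mean band power
#' during baseline epochs, for each canonical frequency band.
#'
#' @param x Signal (uV).
#' @param fs Sampling rate, Hz.
#' @param stim_epochs,baseline_epochs Lists of `list(start, end)` (s) or
#'   two-column matrices.
#' @param bands Named list of bands (default [frequency_bands()]).
#' @param window_s Welch window, s (default 1, so the 1-Hz delta edge is
#'   resolved).
#' @return Named numeric vector of stim/baseline power ratios per band;
#'   `NA` (with warning) for bands with zero baseline power.
#' @export
band_power_portions <- function(x, fs, stim_epochs, baseline_epochs,
                                bands = frequency_bands(), window_s = 1) {
  as_mat <- function(ep) {
    if (is.matrix(ep)) return(ep)
    t(vapply(ep, function(e) c(e$start, e$end), numeric(2)))
  }
  mean_psd <- function(epochs) {
    epochs <- as_mat(epochs)
    check_that(nrow(epochs) > 0, "empty epoch set", "epochs")
    acc <- NULL
    for (i in seq_len(nrow(epochs))) {
      idx <- max(1, round(epochs[i, 1] * fs) + 1):
        min(length(x), round(epochs[i, 2] * fs))
      mw <- movingwin_fft(x[idx], fs, window_s, step_s = window_s / 2)
      p <- rowMeans(mw$power)
      acc <- if (is.null(acc)) p else acc + p
    }
    list(psd = acc / nrow(epochs),
         freqs = (seq_along(acc) - 1) * fs / round(window_s * fs))
  }
  st <- mean_psd(stim_epochs); bl <- mean_psd(baseline_epochs)
  out <- vapply(bands, function(b) {
    sel <- st$freqs >= b[1] & st$freqs <= b[2]
    denom <- sum(bl$psd[sel])
    if (denom == 0) return(NA_real_)
    sum(st$psd[sel]) / denom
  }, numeric(1))
  if (anyNA(out)) warning("zero baseline power in some band(s)")
  out
}

#' Theta frequency versus running speed
#'
#' Pearson R-squared between the per-step dominant theta frequency and the
#' running speed (aligned series, typically restricted to locomotion).
#'
#' @param peak_freq Dominant theta frequency per step, Hz.
#' @param speed Speed per step, cm/s.
#' @return List: `r2`, `r`, `n`. `NA` (with warning) for constant series.
#' @export
theta_speed_relation <- function(peak_freq, speed) {
  check_that(length(peak_freq) == length(speed), "length mismatch", "speed")
  ok <- is.finite(peak_freq) & is.finite(speed)
  f <- peak_freq[ok]; s <- speed[ok]
  if (length(f) < 3 || stats::sd(f) == 0 || stats::sd(s) == 0) {
    warning("theta_speed_relation undefined for constant series")
    return(list(r2 = NA_real_, r = NA_real_, n = length(f)))
  }
  r <- stats::cor(f, s)
  list(r2 = r^2, r = r, n = length(f))
}

#' Quiet-rest mask from the theta/delta ratio
#'
#' Band-passes the signal in the theta (4-12 Hz) and delta (1-4 Hz) bands,
#' takes the Hilbert amplitude envelope of each, z-scores the theta/delta
#' envelope ratio over the session (on a log scale, since the raw ratio's
#' heavy right tail would otherwise drag the mean above the typical value
#' and mark most of any session as rest), and marks as quiet rest the
#' samples where the z-scored ratio is below zero.
#'
#' @param x Signal (uV), at least 10 s.
#' @param fs Sampling rate, Hz.
#' @return Logical vector, `TRUE` during quiet rest, same length as `x`.
#' @export
quiet_rest_mask <- function(x, fs) {
  check_that(length(x) >= 10 * fs, "signal shorter than 10 s", "x")
  th <- Mod(analytic_signal(butter_filtfilt(x, fs, low = 4, high = 12)))
  dl <- Mod(analytic_signal(butter_filtfilt(x, fs, low = 1, high = 4)))
  ratio <- th / pmax(dl, .Machine$double.eps)
  safe_zscore(log(ratio)) < 0
}

#' Detect sharp-wave ripples
#'
#' Band-passes the LFP at 150-250 Hz, forms a detection statistic — the
#' session-z-scored logarithm of the Gaussian-smoothed (10 ms SD) Hilbert
#' amplitude envelope — and finds local maxima of height at least
#' `threshold_sd` standard deviations separated by at least
#' `min_distance_s` (the taller peak wins within that spacing), restricted
#' to quiet-rest samples when a mask is given. The log transform makes the
#' statistic near-Gaussian, so the 4-SD threshold corresponds to a genuine
#' rarity level: on ripple-free Gaussian noise the detector fires
#' essentially never, while injected bursts several background-SDs tall
#' stand far above threshold. Event width is the time the statistic stays
#' above `threshold_sd / 2` around the peak; event power is the peak value
#' of the statistic.
#'
#' @param x Signal (uV).
#' @param fs Sampling rate, Hz (>= 500).
#' @param rest_mask Optional logical quiet-rest mask (same length).
#' @param threshold_sd Peak height threshold, SD units (default 4).
#' @param min_distance_s Minimum inter-peak spacing, s (default 0.03).
#' @param band Ripple band, Hz (default 150-250).
#' @param smooth_s Envelope smoothing SD, s (default 0.01).
#' @return Data frame (`ripple_events`) with `peak_time_s`, `peak_z`,
#'   `width_s`; attributes `rate_per_min` (events per minute of analyzed
#'   time) and `analyzed_s`. Empty (with a warning) for an empty mask.
#' @export
detect_ripples <- function(x, fs, rest_mask = NULL, threshold_sd = 4,
                           min_distance_s = 0.03, band = c(150, 250),
                           smooth_s = 0.01) {
  check_that(fs >= 2 * band[2], "sampling rate too low for the ripple band",
             "fs")
  if (is.null(rest_mask)) rest_mask <- rep(TRUE, length(x))
  empty <- data.frame(peak_time_s = numeric(0), peak_z = numeric(0),
                      width_s = numeric(0))
  analyzed_s <- sum(rest_mask) / fs
  if (analyzed_s == 0) {
    warning("empty rest mask: no samples analyzed")
    attr(empty, "rate_per_min") <- NA_real_
    attr(empty, "analyzed_s") <- 0
    return(empty)
  }
  bp <- butter_filtfilt(x, fs, low = band[1], high = band[2])
  env <- Mod(analytic_signal(bp))
  if (smooth_s > 0) env <- gaussian_smooth(env, smooth_s * fs)
  z <- safe_zscore(log(env + .Machine$double.eps))
  n <- length(z)
  is_peak <- c(FALSE, z[2:(n - 1)] > z[1:(n - 2)] &
                 z[2:(n - 1)] >= z[3:n], FALSE)
  cand <- which(is_peak & z >= threshold_sd & rest_mask)
  if (length(cand) == 0) {
    attr(empty, "rate_per_min") <- 0
    attr(empty, "analyzed_s") <- analyzed_s
    return(empty)
  }
  # enforce minimum spacing, taller peaks first
  keep <- logical(length(cand))
  min_gap <- round(min_distance_s * fs)
  ord <- order(z[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - taken) >= min_gap)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  peaks <- sort(cand[keep])
  half <- threshold_sd / 2
  width <- vapply(peaks, function(p) {
    a <- p; while (a > 1 && z[a - 1] > half) a <- a - 1
    b <- p; while (b < n && z[b + 1] > half) b <- b + 1
    (b - a + 1) / fs
  }, numeric(1))
  out <- data.frame(peak_time_s = (peaks - 1) / fs, peak_z = z[peaks],
                    width_s = width)
  class(out) <- c("ripple_events", "data.frame")
  attr(out, "rate_per_min") <- nrow(out) / (analyzed_s / 60)
  attr(out, "analyzed_s") <- analyzed_s
  out
}

#' Cross-correlation of band-passed signals across channels
#'
#' Normalized cross-correlation of two equally sampled signals after
#' band-pass filtering (theta by default), over lags up to `max_lag_s`.
#'
#' @param a,b Signals (uV), equal length.
#' @param fs Sampling rate, Hz.
#' @param band Band, Hz (default 4-12).
#' @param max_lag_s Maximum lag, s (default 0.1).
#' @return List: `lag_s`, `cor`, `peak_lag_s`, `peak_cor`. Positive peak lag
#'   means `b` lags `a`.
#' @export
cross_channel_xcorr <- function(a, b, fs, band = c(4, 12), max_lag_s = 0.1) {
  check_that(length(a) == length(b), "signals must have equal length", "b")
  fa <- butter_filtfilt(a, fs, low = band[1], high = band[2])
  fb <- butter_filtfilt(b, fs, low = band[1], high = band[2])
  ml <- round(max_lag_s * fs)
  cc <- stats::ccf(fb, fa, lag.max = ml, plot = FALSE)
  lag_s <- as.numeric(cc$lag) / fs
  r <- as.numeric(cc$acf)
  i <- which.max(r)
  list(lag_s = lag_s, cor = r, peak_lag_s = lag_s[i], peak_cor = r[i])
}

#' Phase consistency across stimulation epochs
#'
#' Samples the instantaneous band phase (analytic signal) at a fixed latency
#' after each epoch onset and returns the circular resultant length
#' R in [0, 1]: ~1 when every epoch is phase-reset identically (8 Hz
#' pacing), ~0 for random phases.
#'
#' @param x Signal (uV).
#' @param fs Sampling rate, Hz.
#' @param onsets Epoch onset times, s (at least 2).
#' @param band Band, Hz (default 4-12).
#' @param t_after_s Latency after onset at which phase is sampled, s
#'   (default 0.5).
#' @return List: `r` (resultant length), `phases` (radians per epoch).
#' @export
epoch_phase_consistency <- function(x, fs, onsets, band = c(4, 12),
                                    t_after_s = 0.5) {
  check_that(length(onsets) >= 2, "need at least 2 epochs", "onsets")
  ph_sig <- Arg(analytic_signal(butter_filtfilt(x, fs, low = band[1],
                                                high = band[2])))
  idx <- round((onsets + t_after_s) * fs) + 1
  check_that(all(idx >= 1 & idx <= length(x)),
             "sampled latency outside the signal", "onsets")
  phases <- ph_sig[idx]
  list(r = Mod(mean(exp(1i * phases))), phases = phases)
}
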