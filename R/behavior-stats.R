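#' Recognition index
#'
#' RI = t_novel / (t_novel + t_familiar), the fraction of object-exploration
#' time spent on the novel (displaced) object; 0.5 is chance.
#'
#' @param bouts Either a data frame with columns `object` (`"novel"` /
#'   `"familiar"`) and `duration` (s), or the total novel exploration time
#'   (s) with `t_familiar` supplied.
#' @param t_familiar Total familiar exploration time, s (when `bouts` is
#'   numeric).
#' @return RI in [0, 1]; `NA` (with warning) when total exploration is zero.
#' @export
recognition_index <- function(bouts, t_familiar = NULL) {
  if (is.data.frame(bouts)) {
    check_that(all(c("object", "duration") %in% names(bouts)),
               "need 'object' and 'duration' columns", "bouts")
    check_that(all(bouts$duration > 0), "bout durations must be > 0",
               "bouts")
    t_n <- sum(bouts$duration[bouts$object == "novel"])
    t_f <- sum(bouts$duration[bouts$object == "familiar"])
  } else {
    t_n <- bouts; t_f <- t_familiar
  }
  total <- t_n + t_f
  if (!is.finite(total) || total <= 0) {
    warning("recognition index undefined: zero total exploration")
    return(NA_real_)
  }
  t_n / total
}

#' Linear-track performance
#'
#' Fraction of correct trials (trials containing no error run). Sessions
#' with fewer completed runs than `min_runs` are flagged as excluded.
#'
#' @param trial_correct Logical vector, one entry per completed trial
#'   (incomplete trials' `NA`s are dropped).
#' @param n_runs Number of completed runs in the session (defaults to
#'   4 x trials).
#' @param min_runs Minimum runs for inclusion (default 12).
#' @param runs_per_trial Runs per trial (default 4).
#' @return List: `fraction_correct`, `n_trials`, `n_correct`, `n_runs`,
#'   `included`.
#' @export
track_performance <- function(trial_correct, n_runs = NULL, min_runs = 12,
                              runs_per_trial = 4) {
  trial_correct <- trial_correct[!is.na(trial_correct)]
  check_that(length(trial_correct) >= 1, "zero trials", "trial_correct")
  if (is.null(n_runs)) n_runs <- length(trial_correct) * runs_per_trial
  list(fraction_correct = mean(trial_correct),
       n_trials = length(trial_correct),
       n_correct = sum(trial_correct),
       n_runs = n_runs,
       included = n_runs >= min_runs)
}

#' ANOVA effect sizes from sums of squares
#'
#' eta-squared = SS_between / SS_total (one-way designs) and partial
#' eta-squared = SS_effect / (SS_effect + SS_error) (factorial or
#' repeated-measures designs).
#'
#' @param ss_between,ss_total Sums of squares for eta-squared.
#' @param ss_effect,ss_error Sums of squares for partial eta-squared.
#' @return Named list with `eta2` and/or `partial_eta2` (whichever inputs
#'   were supplied); zero denominators give `NA` with a warning.
#' @export
effect_sizes <- function(ss_between = NULL, ss_total = NULL,
                         ss_effect = NULL, ss_error = NULL) {
  out <- list()
  if (!is.null(ss_between) && !is.null(ss_total)) {
    check_that(ss_between >= 0 && ss_total >= 0 && ss_between <= ss_total,
               "need 0 <= ss_between <= ss_total", "ss_between")
    out$eta2 <- if (ss_total == 0) {
      warning("eta2 undefined: zero total sum of squares"); NA_real_
    } else ss_between / ss_total
  }
  if (!is.null(ss_effect) && !is.null(ss_error)) {
    check_that(ss_effect >= 0 && ss_error >= 0, "must be >= 0", "ss_effect")
    denom <- ss_effect + ss_error
    out$partial_eta2 <- if (denom == 0) {
      warning("partial eta2 undefined: zero denominator"); NA_real_
    } else ss_effect / denom
  }
  check_that(length(out) > 0, "supply sums of squares", "ss_between")
  out
}
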