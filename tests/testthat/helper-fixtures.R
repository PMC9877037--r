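# Small shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

small_track <- function() {
  if (is.null(fixture_env$beh)) {
    cfg <- track_config(n_runs = 16, max_duration_s = 300, error_rate = 0)
    fixture_env$beh <- simulate_track_session(cfg, seed = 42)
  }
  fixture_env$beh
}

# deterministic two-state data with exact conditional rates:
# state 1 and 2 equally occupied, P(A|S1) = p1, P(A|S2) = p2 exactly
two_state_data <- function(n_per_state = 50, p1 = 0.8, p2 = 0.2) {
  bins <- rep(c(1L, 2L), each = n_per_state)
  act <- c(rep(c(1L, 0L), c(round(p1 * n_per_state),
                            n_per_state - round(p1 * n_per_state))),
           rep(c(1L, 0L), c(round(p2 * n_per_state),
                            n_per_state - round(p2 * n_per_state))))
  list(activity = act, bins = bins)
}

binary_entropy <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
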