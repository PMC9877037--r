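#!/usr/bin/env Rscript
# Cross-session field stability (same cells re-recorded vs independently
# re-drawn fields) and the formula-defined behavioral metrics.

suppressPackageStartupMessages(library(thetacode))
dir.create("results", showWarnings = FALSE)

session_curves <- function(seed_beh, seed_pop) {
  beh <- simulate_track_session(track_config(), seed = seed_beh)
  specs <- make_population(n_place = 30, n_time = 15, n_distance = 10,
                           n_untuned = 15, seed = seed_pop)
  sim <- simulate_neurons(beh, specs, seed = seed_beh + 500)
  b <- binarize_traces(sim$neural$traces, sim$neural$frame_rate)
  cls <- classify_session(b, beh, n_shuffles = 300, seed = seed_beh + 600)
  attr(cls, "curves")
}
# same tuning re-expressed on a new day vs fields re-drawn from scratch
day1 <- session_curves(31, 900)
day2_same <- session_curves(32, 900)
day2_remap <- session_curves(33, 901)
stable <- compare_sessions(day1, day2_same)
remap <- compare_sessions(day1, day2_remap)
for (v in c("location", "time", "distance")) {
  col <- paste0("stability_", v)
  cat(sprintf("%-9s field stability: same cells %.2f, re-drawn %.2f\n", v,
              mean(stable[[col]], na.rm = TRUE),
              mean(remap[[col]], na.rm = TRUE)))
}
write.table(stable, "results/stability_same_cells.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# behavioral metrics defined by formula
beh <- read_behavior("results/session/behavior.tsv")
tc <- unique(beh$trial_correct[beh$trial_id > 0 & !is.na(beh$trial_correct)])
perf <- track_performance(tapply(beh$trial_correct, beh$trial_id,
                                 function(x) x[1])[-1])
cat(sprintf("\ntrack performance: %d/%d correct trials = %.2f\n",
            perf$n_correct, perf$n_trials, perf$fraction_correct))
bouts <- data.frame(object = rep(c("novel", "familiar"), c(4, 3)),
                    duration = c(3.1, 2.4, 1.8, 2.2, 2.0, 1.6, 1.9))
cat(sprintf("recognition index (example bouts): %.2f\n",
            recognition_index(bouts)))
es <- effect_sizes(ss_between = 12.4, ss_total = 40.1,
                   ss_effect = 12.4, ss_error = 27.7)
cat(sprintf("eta-squared %.2f, partial eta-squared %.2f\n",
            es$eta2, es$partial_eta2))
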