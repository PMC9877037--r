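#!/usr/bin/env Rscript
# Naive Bayes decoding of location, elapsed time and distance from the
# binarized population: 90/10 trial-wise split, 2-s temporal filtering,
# 50 bootstraps of 160 cells, z-scored against circularly shuffled
# surrogates.

suppressPackageStartupMessages(library(thetacode))
ses <- "results/session"
beh <- read_behavior(file.path(ses, "behavior.tsv"))
tr <- read_traces(file.path(ses, "traces.tsv"))
binary <- binarize_traces(tr$traces, tr$frame_rate)
loco <- beh$speed_cm_s > 5

vals <- list(location = beh$x_cm, time = beh$elapsed_s,
             distance = beh$distance_cm)
rows <- list()
for (v in names(vals)) {
  res <- bootstrap_decode(binary, vals[[v]], binning_spec(v), use = loco,
                          n_boot = 50, cells_per_boot = 160,
                          split_by = beh$trial_id,
                          frame_rate = tr$frame_rate,
                          seed = 10 + match(v, names(vals)))
  unit <- if (v == "time") "s" else "cm"
  cat(sprintf("%-9s error %6.2f %s vs shuffled %6.2f %s  (z = %.2f)\n",
              v, res$mean_error, unit, res$mean_shuffled_error, unit,
              res$z))
  rows[[v]] <- data.frame(variable = v, mean_error = res$mean_error,
                          shuffled_error = res$mean_shuffled_error,
                          z = res$z, n_boot = 50, cells_per_boot = 160)
}
write.table(do.call(rbind, rows), "results/decoding_summary.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nnegative z: decoding error far below the shuffled-surrogate error\n")
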