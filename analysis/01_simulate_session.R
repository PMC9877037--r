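#!/usr/bin/env Rscript
# Simulate one linear-track imaging session with known ground truth:
# behavior (134-cm track, three-tone trial structure, reward every 4th run),
# a mixed population of place/time/distance-tuned and untuned neurons, and
# a speed-coupled LFP. Writes the session to results/session/ in the
# package's text formats so the later stages can re-read it.

suppressPackageStartupMessages(library(thetacode))
out <- "results/session"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

cfg <- track_config()  # study defaults: 15-min budget, realistic dawdling
beh <- simulate_track_session(cfg, seed = seed)
specs <- make_population(n_place = 50, n_time = 30, n_distance = 20,
                         n_untuned = 50, seed = seed + 100)
sim <- simulate_neurons(beh, specs, seed = seed + 200)
lfp <- simulate_lfp(lfp_plan(duration_s = floor(max(beh$time_s)), fs = 1000),
                    speed = beh$speed_cm_s, seed = seed + 300)

write_behavior(beh, file.path(out, "behavior.tsv"))
write_traces(sim$neural$traces, sim$neural$frame_rate,
             file.path(out, "traces.tsv"))
write_lfp(lfp$lfp, file.path(out, "lfp.tsv"))
jsonlite::write_json(list(classes = sim$truth$classes, seed = seed),
                     file.path(out, "truth.json"), auto_unbox = TRUE)

runs <- attr(beh, "runs")
perf <- track_performance(attr(beh, "trials")$correct, n_runs = nrow(runs))
cat(sprintf("session: %.1f min, %d runs, %d trials\n",
            max(beh$time_s) / 60, nrow(runs), perf$n_trials))
cat(sprintf("performance: %.0f%% correct trials (min-12-runs filter: %s)\n",
            100 * perf$fraction_correct,
            if (perf$included) "included" else "excluded"))
cat(sprintf("locomotion (>5 cm/s): %.0f%% of frames\n",
            100 * mean(beh$locomotion)))
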