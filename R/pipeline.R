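#' End-to-end synthetic pipeline run
#'
#' Orchestrates generation and analysis from a single config: simulate a
#' linear-track session and a tuned population, binarize, classify every
#' cell (tuning curves, MI, circular shuffles), bootstrap-decode each
#' variable, and optionally simulate and analyze an LFP trace. All
#' randomness flows from `config$seed`; re-running the same config
#' reproduces every table bit-identically. Results and a provenance
#' manifest (config hash + seeds + stage timings) are written under
#' `out_dir` when given.
#'
#' @param config Nested list; see Details. Missing entries fall back to the
#'   documented defaults of the underlying functions.
#' @param out_dir Optional output directory for tables and the manifest.
#' @param stages Character subset of `c("synth", "classify", "decode",
#'   "lfp")` (classification implies synthesis).
#' @param quiet Suppress progress messages.
#' @details Config entries: `seed` (master seed); `track` (arguments of
#'   [track_config()]); `population` (arguments of [make_population()]);
#'   `neurons` (`calcium_tau`, `noise_sd`); `classify` (`alpha`,
#'   `n_shuffles`); `decode` (`n_boot`, `cells_per_boot`, `window_s`,
#'   `method`); `lfp` (arguments of [lfp_plan()], minus duration which is
#'   taken from the session).
#' @return List: `behavior`, `neural` (with `$binary`), `truth`,
#'   `classification` (per-cell table), `decoding` (per-variable summary
#'   data frame + full results), `lfp` (signal, OS per epoch type,
#'   theta-speed R2), `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL,
                         stages = c("synth", "classify", "decode", "lfp"),
                         quiet = FALSE) {
  t0 <- Sys.time()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  clock <- function(stage, expr) {
    t1 <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t1, units = "secs"))
    res
  }

  say("synth: simulating track session (seed %d)", seed)
  cfg <- do.call(track_config, config$track %||% list())
  beh <- clock("synth_behavior", simulate_track_session(cfg, seed))
  pop_args <- config$population %||% list()
  pop_args$seed <- derive_seed(seed, 1)
  specs <- do.call(make_population, pop_args)
  neuro_args <- config$neurons %||% list()
  sim <- clock("synth_neurons",
               do.call(simulate_neurons,
                       c(list(behavior = beh, specs = specs,
                              seed = derive_seed(seed, 2)), neuro_args)))
  neural <- sim$neural
  neural$binary <- binarize_traces(neural$traces, neural$frame_rate)

  out <- list(behavior = beh, neural = neural, truth = sim$truth,
              config = config)

  if ("classify" %in% stages) {
    cls_args <- config$classify %||% list()
    say("classify: %d cells x 3 variables", nrow(neural$binary))
    out$classification <- clock("classify",
      do.call(classify_session,
              c(list(binary = neural$binary, behavior = beh,
                     seed = derive_seed(seed, 3)), cls_args)))
    out$classification$true_class <- sim$truth$classes
  }

  if ("decode" %in% stages) {
    dec_args <- config$decode %||% list()
    fr <- attr(beh, "frame_rate")
    loco <- beh$speed_cm_s > 5
    values <- list(location = beh$x_cm, time = beh$elapsed_s,
                   distance = beh$distance_cm)
    summ <- list()
    out$decoding <- list()
    for (v in names(values)) {
      say("decode: %s", v)
      res <- clock(paste0("decode_", v),
        do.call(bootstrap_decode,
                c(list(binary = neural$binary, values = values[[v]],
                       spec = binning_spec(v), use = loco,
                       split_by = beh$trial_id, frame_rate = fr,
                       seed = derive_seed(seed, 4)), dec_args)))
      out$decoding[[v]] <- res
      summ[[v]] <- data.frame(variable = v, mean_error = res$mean_error,
                              shuffled_error = res$mean_shuffled_error,
                              z = res$z)
    }
    out$decoding_summary <- do.call(rbind, summ)
    rownames(out$decoding_summary) <- NULL
  }

  if ("lfp" %in% stages) {
    say("lfp: simulating and analyzing")
    lfp_args <- config$lfp %||% list()
    lfp_args$duration_s <- lfp_args$duration_s %||%
      min(60, max(beh$time_s))
    plan <- do.call(lfp_plan, lfp_args)
    lsim <- clock("synth_lfp",
                  simulate_lfp(plan, speed = beh$speed_cm_s,
                               speed_frame_rate = attr(beh, "frame_rate"),
                               seed = derive_seed(seed, 5)))
    os <- oscillation_strength(lsim$lfp$samples[seq_len(5 * plan$fs)],
                               plan$fs)
    th <- movingwin_spectrum(lsim$lfp$samples, plan$fs)
    sp <- stats::approx(beh$time_s, beh$speed_cm_s, xout = th$times,
                        rule = 2)$y
    run <- sp > 5
    out$lfp <- list(signal = lsim$lfp, truth = lsim$truth,
                    os_first_epoch = as.numeric(os),
                    theta_speed = theta_speed_relation(
                      th$dominant_freq[run], sp[run]))
  }

  out$manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    stages = stages,
    timings_s = timings,
    created = format(t0, "%Y-%m-%d %H:%M:%S")
  )
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of a config: md5 of its canonical JSON serialization.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$classification))
    utils::write.table(run$classification,
                       file.path(out_dir, "classification.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$decoding_summary))
    utils::write.table(run$decoding_summary,
                       file.path(out_dir, "decoding_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Cross-session field stability
#'
#' Pairwise field correlation ([field_stability()]) between matched cells
#' of two sessions, given a cell mapping (identity on synthetic data; an
#' external registration table otherwise).
#'
#' @param curves_a,curves_b Cells-by-bins tuning-curve matrices (e.g. the
#'   `curves` attribute of [classify_session()], one variable), or lists of
#'   such matrices keyed by variable.
#' @param mapping Two-column matrix/data frame of matched cell indices
#'   (`a`, `b`); defaults to identity when `NULL` and the two sessions have
#'   equally many cells.
#' @return Data frame with `cell_a`, `cell_b`, and one stability column per
#'   variable, plus a `group_means` attribute.
#' @export
compare_sessions <- function(curves_a, curves_b, mapping = NULL) {
  if (is.matrix(curves_a)) curves_a <- list(value = curves_a)
  if (is.matrix(curves_b)) curves_b <- list(value = curves_b)
  na <- nrow(curves_a[[1]])
  if (is.null(mapping)) {
    check_that(na == nrow(curves_b[[1]]),
               "mapping required when cell counts differ", "mapping")
    mapping <- cbind(seq_len(na), seq_len(na))
  }
  mapping <- as.matrix(mapping)
  check_that(nrow(mapping) > 0, "empty mapping", "mapping")
  out <- data.frame(cell_a = mapping[, 1], cell_b = mapping[, 2])
  for (v in names(curves_a)) {
    out[[paste0("stability_", v)]] <- vapply(seq_len(nrow(mapping)),
      function(i) suppressWarnings(
        field_stability(curves_a[[v]][mapping[i, 1], ],
                        curves_b[[v]][mapping[i, 2], ])),
      numeric(1))
  }
  stab_cols <- grep("^stability_", names(out))
  attr(out, "group_means") <- colMeans(out[stab_cols], na.rm = TRUE)
  out
}
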