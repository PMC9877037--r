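#' Write / read a behavior table
#'
#' Behavior is stored as tidy tab-delimited text, one row per frame, with
#' the session attributes (frame rate, track length) in a JSON sidecar.
#'
#' @param behavior A `session_behavior` data frame.
#' @param path Output file (`.tsv`); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.table(as.data.frame(behavior), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(frame_rate = attr(behavior, "frame_rate"),
               track_length = attr(behavior, "track_length"),
               arena_cm = attr(behavior, "arena_cm"))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  beh <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in names(meta)) attr(beh, nm) <- meta[[nm]]
  }
  class(beh) <- c("session_behavior", "data.frame")
  beh
}

#' Write / read a trace matrix
#'
#' Dense numeric matrix (rows = cells), tab-delimited, with a JSON sidecar
#' holding the frame rate and cell ids.
#'
#' @param traces Cells-by-frames matrix.
#' @param frame_rate Hz.
#' @param path Output file; sidecar is `<path>.json`.
#' @export
write_traces <- function(traces, frame_rate, path) {
  utils::write.table(traces, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(frame_rate = frame_rate,
                            cell_ids = seq_len(nrow(traces)),
                            n_frames = ncol(traces)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(traces = m, frame_rate = meta$frame_rate)
}

#' Write / read an LFP trace
#'
#' Two-column tab-delimited text: `time_s`, `uv`.
#'
#' @param lfp An `lfp_signal` (list with `samples`, `fs`).
#' @param path Output file.
#' @export
write_lfp <- function(lfp, path) {
  utils::write.table(data.frame(time_s = (seq_along(lfp$samples) - 1) /
                                  lfp$fs,
                                uv = lfp$samples),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  fs <- round(1 / stats::median(diff(d$time_s)))
  structure(list(samples = d$uv, fs = fs, time_s = d$time_s,
                 stim_epochs = list(), channel = basename(path)),
            class = "lfp_signal")
}
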