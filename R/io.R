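#' Write / read a tracking series as CSV
#'
#' Columns: `t, x, y, speed, heading_deg, light_on, trial_id`. The frame rate
#' is recorded in a `# frame_rate:` header comment and restored on read.
#'
#' @param track a `tracking_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate: %g", attr(track, "frame_rate")), con)
  out <- data.frame(t = track$t, x = track$x, y = track$y, speed = track$speed,
                    heading_deg = track$heading, light_on = track$light_on,
                    trial_id = track$trial_id)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @export
read_tracking_csv <- function(path) {
  first <- readLines(path, n = 1)
  fr <- if (startsWith(first, "# frame_rate:"))
    as.numeric(sub("# frame_rate:", "", first)) else NA_real_
  df <- utils::read.csv(path, comment.char = "#")
  out <- data.frame(t = df$t, x = df$x, y = df$y, speed = df$speed,
                    heading = df$heading_deg, light_on = as.logical(df$light_on),
                    trial_id = df$trial_id,
                    is_rest = is.na(df$trial_id))
  attr(out, "frame_rate") <- fr
  class(out) <- c("tracking_series", "data.frame")
  out
}

#' Write / read a trace container (plain-text)
#'
#' Stores the soma and neuropil fluorescence matrices (and optionally the
#' ground-truth spikes) as TSV files in a directory, with frame rate, seed
#' and provenance in a JSON metadata file.
#'
#' @param traces a `roi_trace_set`.
#' @param dir container directory (created if needed).
#' @param true_spikes optional ground-truth spike matrix.
#' @param seed optional seed to record.
#' @return `dir`, invisibly.
#' @export
write_trace_container <- function(traces, dir, true_spikes = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    m, file.path(dir, f), sep = "\t", row.names = FALSE, col.names = FALSE)
  wm(traces$F_soma, "F_soma.tsv")
  wm(traces$F_neuropil, "F_neuropil.tsv")
  if (!is.null(true_spikes)) wm(true_spikes, "true_spikes.tsv")
  meta <- list(frame_rate = traces$frame_rate, provenance = traces$provenance,
               n_cells = nrow(traces$F_soma), n_frames = ncol(traces$F_soma))
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_trace_container
#' @export
read_trace_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rm_ <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  traces <- structure(
    list(F_soma = unname(rm_("F_soma.tsv")),
         F_neuropil = unname(rm_("F_neuropil.tsv")),
         frame_rate = meta$frame_rate,
         provenance = "file"),
    class = "roi_trace_set")
  spk_path <- file.path(dir, "true_spikes.tsv")
  list(traces = traces,
       true_spikes = if (file.exists(spk_path)) unname(rm_("true_spikes.tsv")) else NULL,
       meta = meta)
}

# TSV with a header comment recording the configuration hash
write_stage_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(sprintf("# config: %s", config_hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
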