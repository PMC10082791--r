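#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its standard default
#' (60 heading bins, ~15-degree smoothing realised as a 3-bin window, 1000
#' shuffles, 99th/90th shuffle percentiles, KS p < 0.1, Cohen's d > 0.8,
#' duplicate-ROI r > 0.5, 200 time bins per trial, 18-degree accuracy window,
#' 1000 bootstrap iterations) together with the synthetic-session parameters.
#' All values can be overridden; the configuration is echoed into every
#' output file via its hash. `n_shuffles` and `n_boot` default to 200 for
#' desk-scale runs; set them to 1000 to match the full protocol.
#'
#' @param ... overrides for any configuration entry.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # session
    n_cells = 300, n_repeats = 6, rotation_speed = 5, rotation_duration = 96,
    rest_duration = 5, frame_rate = 10, cue_layout = "dual_symmetric",
    # synthesis
    class_mix = c(heading = 0.121 * 0.39, landmark = 0.121 * 0.33,
                  alignment = 0.121 * 0.28, untuned = 0.879),
    peak_rate = 10, baseline_rate = 0.5, tuning_width_deg = 35,
    noise_sd = 0.05,
    remap_offset_deg = 90, remap_incoherent_fraction = 0,
    # analysis thresholds
    n_bins = 60, smooth_bins = 3, n_shuffles = 200, rvl_percentile = 99,
    r2_percentile = 90, ks_alpha = 0.1, d_threshold = 0.8, r_threshold = 0.5,
    resample_bins = 200, accuracy_window_deg = 18, n_boot = 200,
    chance_accuracy = 0.10, k_range = 2:8,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$n_cells < 1) stop("n_cells must be positive")
  structure(cfg, class = "pipeline_config")
}

# tiny polynomial rolling hash for provenance stamps (stays in exact-double
# integer range)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic-session analysis pipeline
#'
#' Orchestrates simulate -> process -> tune -> remap -> classify -> decode,
#' writing each stage's tables into `out_dir` with the configuration hash in
#' every header. Stages are resumable: a stage whose `.done` sentinel exists
#' is skipped on rerun. With a fixed seed the result tables are
#' byte-identical across reruns.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @param stages subset of stages to run (default all, in order).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "process", "tune", "remap",
                                    "classify", "decode")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  state <- new.env(parent = emptyenv())
  done <- function(st) file.path(out_dir, paste0(st, ".done"))
  message_stage <- function(st) message(sprintf("[%s] stage %s", hash, st))

  load_simulate <- function() {
    state$track <- read_tracking_csv(file.path(out_dir, "tracking.csv"))
    cont <- read_trace_container(file.path(out_dir, "traces"))
    state$traces <- cont$traces
    state$spikes_true <- cont$true_spikes
    state$pop <- utils::read.delim(file.path(out_dir, "population.tsv"),
                                   comment.char = "#")
    class(state$pop) <- c("ground_truth_population", "data.frame")
  }

  if ("simulate" %in% stages && !file.exists(done("simulate"))) {
    message_stage("simulate")
    sc <- session_config(mode = "controlled_rotation",
                         n_repeats = config$n_repeats,
                         rotation_speed = config$rotation_speed,
                         rotation_duration = config$rotation_duration,
                         rest_duration = config$rest_duration,
                         frame_rate = config$frame_rate,
                         cue_layout = config$cue_layout,
                         seed = config$seed)
    track <- generate_session(sc)
    pop <- generate_population(config$n_cells, class_mix = config$class_mix,
                               peak_rate = config$peak_rate,
                               baseline_rate = config$baseline_rate,
                               tuning_width_deg = config$tuning_width_deg,
                               noise_sd = config$noise_sd, seed = config$seed)
    sim <- simulate_traces(pop, track, seed = config$seed + 1L)
    write_tracking_csv(track, file.path(out_dir, "tracking.csv"))
    write_trace_container(sim$traces, file.path(out_dir, "traces"),
                          true_spikes = sim$spikes, seed = config$seed)
    write_stage_tsv(as.data.frame(unclass(pop)),
                    file.path(out_dir, "population.tsv"), hash)
    file.create(done("simulate"))
  }
  if (any(c("process", "tune", "remap", "classify", "decode") %in% stages)) {
    if (!file.exists(done("simulate")))
      stop("stage 'process' is missing its input: run 'simulate' first")
    load_simulate()
  }

  if ("process" %in% stages && !file.exists(done("process"))) {
    message_stage("process")
    proc <- process_traces(state$traces, r_threshold = config$r_threshold)
    qc <- data.frame(cell_id = seq_along(proc$alpha), alpha = proc$alpha,
                     F0 = proc$F0, gamma = proc$gamma,
                     n_spikes = rowSums(proc$spikes > 0),
                     kept = seq_along(proc$alpha) %in% proc$kept)
    write_stage_tsv(qc, file.path(out_dir, "qc.tsv"), hash)
    utils::write.table(proc$spikes, file.path(out_dir, "spikes.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    file.create(done("process"))
  }
  get_spikes <- function() as.matrix(unname(utils::read.table(
    file.path(out_dir, "spikes.tsv"), sep = "\t")))

  if ("tune" %in% stages && !file.exists(done("tune"))) {
    if (!file.exists(done("process"))) stop("stage 'tune' needs 'process'")
    message_stage("tune")
    spikes <- get_spikes()
    curves <- compute_tuning_curves(spikes, state$track,
                                    n_bins = config$n_bins,
                                    smooth_bins = config$smooth_bins)
    set.seed(config$seed + 2L)
    sel <- selectivity_table(curves, n_shuffles = config$n_shuffles,
                             n_terms = if (config$cue_layout == "single") 1 else 2,
                             ks_alpha = config$ks_alpha,
                             d_threshold = config$d_threshold,
                             r2_percentile = config$r2_percentile)
    write_stage_tsv(sel, file.path(out_dir, "selectivity.tsv"), hash)
    file.create(done("tune"))
  }
  get_sel <- function() utils::read.delim(file.path(out_dir, "selectivity.tsv"),
                                          comment.char = "#")

  if ("remap" %in% stages && !file.exists(done("remap"))) {
    if (!file.exists(done("tune"))) stop("stage 'remap' needs 'tune'")
    message_stage("remap")
    # context B: same cells, wall cues replaced -> coherent rotation
    pop_b <- apply_remap(state$pop, config$remap_offset_deg,
                         config$remap_incoherent_fraction,
                         seed = config$seed + 3L)
    sim_b <- simulate_traces(pop_b, state$track, seed = config$seed + 4L)
    sel <- get_sel()
    tuned <- which(sel$selective)
    if (length(tuned) >= 2L) {
      curves_b <- compute_tuning_curves(sim_b$spikes[tuned, , drop = FALSE],
                                        state$track, n_bins = config$n_bins,
                                        smooth_bins = config$smooth_bins)
      pref_b <- vapply(curves_b, preferred_direction, numeric(1))
      rem <- delta_phase_offset(sel$preferred_deg[tuned], pref_b)
      rem <- cbind(cell_id = tuned, rem)
      write_stage_tsv(rem, file.path(out_dir, "remapping.tsv"), hash)
    }
    spikes <- get_spikes()
    curves_on <- compute_tuning_curves(spikes, state$track, condition = "light_on",
                                       n_bins = config$n_bins,
                                       smooth_bins = config$smooth_bins)
    curves_off <- compute_tuning_curves(spikes, state$track, condition = "light_off",
                                        n_bins = config$n_bins,
                                        smooth_bins = config$smooth_bins)
    fs <- do.call(rbind, lapply(seq_along(curves_on), function(i) {
      f_on <- flip_score(curves_on[[i]])
      f_off <- flip_score(curves_off[[i]])
      data.frame(cell_id = i,
                 condition = c("light_on", "light_off"),
                 cc180 = c(f_on$cc180, f_off$cc180),
                 cc90 = c(f_on$cc90, f_off$cc90),
                 cc270 = c(f_on$cc270, f_off$cc270),
                 flip = c(f_on$flip, f_off$flip))
    }))
    write_stage_tsv(fs, file.path(out_dir, "flip_scores.tsv"), hash)
    file.create(done("remap"))
  }

  if ("classify" %in% stages && !file.exists(done("classify"))) {
    if (!file.exists(done("tune"))) stop("stage 'classify' needs 'tune'")
    message_stage("classify")
    spikes <- get_spikes()
    sel <- get_sel()
    tuned <- which(sel$selective)
    if (length(tuned) < 30L)
      stop("fewer than 30 selective cells; classification is unreliable")
    cl <- classify_population(spikes[tuned, , drop = FALSE], state$track,
                              k_range = config$k_range,
                              seed = config$seed + 5L)
    tab <- data.frame(cell_id = tuned,
                      cluster_id = cl$clustering$cluster_ids,
                      label = cl$assignment$label)
    write_stage_tsv(tab, file.path(out_dir, "classes.tsv"), hash)
    arch <- do.call(rbind, lapply(seq_along(cl$assignment$archetypes), function(g) {
      a <- cl$assignment$archetypes[[g]]
      data.frame(cluster = g, label = a$label,
                 bin = seq_along(a$curve_on),
                 curve_on = a$curve_on, curve_off = a$curve_off)
    }))
    write_stage_tsv(arch, file.path(out_dir, "archetypes.tsv"), hash)
    feats <- cl$features$features
    proj <- tryCatch(
      lda_project(feats, cl$assignment$label),
      error = function(e) NULL)
    if (!is.null(proj)) {
      write_stage_tsv(data.frame(cell_id = tuned, ld1 = proj$coords[, 1],
                                 ld2 = proj$coords[, 2],
                                 label = cl$assignment$label),
                      file.path(out_dir, "lda.tsv"), hash)
    }
    jsonlite::write_json(
      list(k_selected = cl$clustering$k_selected,
           silhouette = as.list(cl$clustering$silhouette),
           seed = config$seed + 5L, config = hash),
      file.path(out_dir, "classify_meta.json"), auto_unbox = TRUE, digits = NA)
    file.create(done("classify"))
  }

  if ("decode" %in% stages && !file.exists(done("decode"))) {
    if (!file.exists(done("classify"))) stop("stage 'decode' needs 'classify'")
    message_stage("decode")
    spikes <- get_spikes()
    classes <- utils::read.delim(file.path(out_dir, "classes.tsv"),
                                 comment.char = "#")
    labels <- rep("untuned", nrow(spikes))
    labels[classes$cell_id] <- classes$label
    aligned <- resample_trials(spikes, state$track, n_out = config$resample_bins)
    filters <- c("all_tuned", "heading", "landmark", "alignment")
    rows <- list(); summ <- list()
    for (f in filters) {
      if (f != "all_tuned" && sum(labels == f) == 0) next
      dec <- decode_population(aligned, labels, class_filter = f,
                               n_boot = config$n_boot,
                               seed = config$seed + 6L)
      rows[[f]] <- data.frame(iteration = seq_len(config$n_boot), class = f,
                              accuracy_on = dec$accuracy_on,
                              accuracy_off = dec$accuracy_off)
      summ[[f]] <- list(light_on = dec$summary_on, light_off = dec$summary_off,
                        n_sample = dec$n_sample)
    }
    write_stage_tsv(do.call(rbind, rows), file.path(out_dir, "decoding.tsv"), hash)
    jsonlite::write_json(c(summ, list(chance = config$chance_accuracy,
                                      config = hash)),
                         file.path(out_dir, "decode_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    file.create(done("decode"))
  }
  invisible(out_dir)
}

#' Render a summary report for a completed pipeline run
#'
#' Produces a multi-panel PDF: tuning heat map sorted by cross-validated peak,
#' delta-phase-offset histogram, LDA cluster scatter, and class-wise decoder
#' accuracy with bootstrap CIs and the 0.10 chance line.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param file output PDF path (default `report.pdf` inside `run_dir`).
#' @return the report path, invisibly.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report.pdf")) {
  need <- c(simulate = "tracking.csv", process = "spikes.tsv",
            tune = "selectivity.tsv", classify = "classes.tsv",
            decode = "decode_summary.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run; missing stages: ",
         paste(names(missing), collapse = ", "))
  track <- read_tracking_csv(file.path(run_dir, "tracking.csv"))
  spikes <- as.matrix(unname(utils::read.table(file.path(run_dir, "spikes.tsv"),
                                               sep = "\t")))
  sel <- utils::read.delim(file.path(run_dir, "selectivity.tsv"), comment.char = "#")
  summ <- jsonlite::read_json(file.path(run_dir, "decode_summary.json"),
                              simplifyVector = TRUE)
  grDevices::pdf(file, width = 9, height = 7)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  # panel 1: heat map of selective cells sorted by preferred direction
  tuned <- which(sel$selective)
  if (length(tuned) >= 2) {
    curves <- compute_tuning_curves(spikes[tuned, , drop = FALSE], track)
    m <- t(vapply(curves, function(cv) {
      y <- cv$mean_curve; y[is.na(y)] <- 0
      if (max(y) > 0) y / max(y) else y
    }, numeric(60)))
    ord <- order(sel$preferred_deg[tuned])
    graphics::image(x = bin_centers_deg(60), y = seq_along(tuned),
                    z = t(m[ord, , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "heading (deg)", ylab = "cell (sorted by peak)",
                    main = "tuning, selective cells")
  } else graphics::plot.new()
  # panel 2: delta-phase-offset histogram
  remap_path <- file.path(run_dir, "remapping.tsv")
  if (file.exists(remap_path)) {
    rem <- utils::read.delim(remap_path, comment.char = "#")
    graphics::hist(rem$delta_phase_offset, breaks = seq(-180, 180, by = 20),
                   col = "grey70", xlab = expression(Delta ~ "phase offset (deg)"),
                   main = "coherent remapping")
    graphics::abline(v = 0, lty = 2)
  } else graphics::plot.new()
  # panel 3: LDA scatter
  lda_path <- file.path(run_dir, "lda.tsv")
  if (file.exists(lda_path)) {
    ld <- utils::read.delim(lda_path, comment.char = "#")
    cls <- factor(ld$label)
    graphics::plot(ld$ld1, ld$ld2, col = as.integer(cls) + 1, pch = 19,
                   xlab = "LD1", ylab = "LD2", main = "functional classes (LDA)")
    graphics::legend("topright", legend = levels(cls),
                     col = seq_along(levels(cls)) + 1, pch = 19, cex = 0.8)
  } else graphics::plot.new()
  # panel 4: decoder accuracy per class with CIs and chance line
  chance <- summ$chance
  classes <- setdiff(names(summ), c("chance", "config"))
  if (length(classes)) {
    mk <- function(cl, cond) {
      s <- summ[[cl]][[cond]]
      if (is.null(s)) c(NA, NA, NA) else c(s$mean, s$ci_low, s$ci_high)
    }
    vals <- cbind(sapply(classes, mk, "light_on"),
                  sapply(classes, mk, "light_off"))
    x <- seq_len(ncol(vals))
    graphics::plot(x, vals[1, ], ylim = c(0, 1), pch = 19,
                   xaxt = "n", xlab = "", ylab = "decoder accuracy",
                   main = "pseudopopulation decoding")
    graphics::axis(1, at = x, labels = paste(rep(classes, 2),
                   rep(c("on", "off"), each = length(classes))), las = 2, cex.axis = 0.7)
    graphics::arrows(x, vals[2, ], x, vals[3, ], angle = 90, code = 3, length = 0.03)
    graphics::abline(h = chance, lty = 2, col = "darkgreen")
  } else graphics::plot.new()
  invisible(file)
}
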