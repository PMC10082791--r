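#' Session configuration for synthetic chamber experiments
#'
#' Describes one imaging session in the rotating-chamber paradigm: a head-fixed
#' animal whose visual environment rotates under experimenter control
#' (`mode = "controlled_rotation"`), or an animal steering a floating chamber
#' (`mode = "voluntary"`). Controlled sessions consist of `n_repeats` rotation
#' blocks of `rotation_duration` seconds at `rotation_speed` rpm, separated by
#' `rest_duration` second rests during which the chamber is stationary and the
#' room lights may be switched. The first repeat is always performed with the
#' lights on.
#'
#' @param mode `"controlled_rotation"` or `"voluntary"`.
#' @param n_repeats number of rotation blocks (2-6 in the emulated protocol).
#' @param rotation_speed chamber rotation speed in rpm (3-7 typical).
#' @param rotation_duration duration of each rotation block in seconds
#'   (90-120 typical; must cover at least one full turn).
#' @param rest_duration stationary rest between blocks, seconds.
#' @param frame_rate imaging frame rate, Hz.
#' @param light_schedule character vector of `"on"`/`"off"`, one per repeat;
#'   default alternates on/off starting with on.
#' @param cue_layout `"single"` (one wall cue) or `"dual_symmetric"` (two
#'   identical cues 180 degrees apart).
#' @param rotation_jitter fractional frame-to-frame variability of the
#'   rotation speed (default 0.02), emulating the minor speed variations of
#'   the physical chamber; set 0 for perfectly rigid rotation.
#' @param duration total session length in seconds (voluntary mode only).
#' @param persistence heading persistence of the voluntary angular random walk,
#'   in [0, 1); higher values give smoother trajectories.
#' @param context_id label for the visual context (used by remapping analyses).
#' @param seed integer seed; every generator call is deterministic given it.
#' @return a `session_config` list.
#' @export
session_config <- function(mode = c("controlled_rotation", "voluntary"),
                           n_repeats = 4,
                           rotation_speed = 5,
                           rotation_duration = 96,
                           rest_duration = 5,
                           frame_rate = 10,
                           light_schedule = NULL,
                           cue_layout = c("dual_symmetric", "single"),
                           rotation_jitter = 0.02,
                           duration = 600,
                           persistence = 0.9,
                           context_id = "A",
                           seed = 1L) {
  mode <- match.arg(mode)
  cue_layout <- match.arg(cue_layout)
  if (n_repeats < 1 || rotation_duration <= 0 || rest_duration < 0 ||
      frame_rate <= 0 || rotation_speed <= 0 || duration <= 0)
    stop("invalid session configuration: durations, rates and counts must be positive")
  if (is.null(light_schedule))
    light_schedule <- rep(c("on", "off"), length.out = n_repeats)
  if (length(light_schedule) != n_repeats)
    stop("light_schedule must have one entry per repeat")
  if (!all(light_schedule %in% c("on", "off")))
    stop("light_schedule entries must be 'on' or 'off'")
  if (light_schedule[1L] != "on")
    stop("the first repeat must be light-on")
  if (mode == "controlled_rotation" &&
      rotation_speed / 60 * rotation_duration < 1)
    stop("rotation block must cover at least one full 360-degree turn")
  structure(
    list(mode = mode, n_repeats = n_repeats, rotation_speed = rotation_speed,
         rotation_duration = rotation_duration, rest_duration = rest_duration,
         frame_rate = frame_rate, light_schedule = light_schedule,
         cue_layout = cue_layout, rotation_jitter = rotation_jitter,
         duration = duration,
         persistence = persistence, context_id = context_id,
         seed = as.integer(seed)),
    class = "session_config")
}

#' Generate a synthetic chamber-tracking series
#'
#' Produces the per-frame chamber state for a session: time, position, speed,
#' heading (degrees in [0, 360)), light state, and trial labels. In controlled
#' mode the heading advances at the configured rpm during rotation blocks and
#' is constant during rests; each completed 360-degree sweep is one trial, so
#' every trial visits all 60 heading bins. Rest frames and incomplete final
#' sweeps carry `trial_id = NA`. Light transitions occur only during rests.
#'
#' Voluntary mode is a bounded angular random walk with persistence, paired
#' with a positional random walk inside a 150 mm radius arena.
#'
#' @param config a [session_config()].
#' @return a data frame of class `tracking_series` with columns `t`, `x`, `y`,
#'   `speed`, `heading`, `light_on`, `trial_id`, `is_rest`, and attributes
#'   `frame_rate`, `config`.
#' @export
generate_session <- function(config) {
  if (!inherits(config, "session_config")) stop("config must be a session_config")
  set.seed(config$seed)
  fr <- config$frame_rate
  dt <- 1 / fr
  if (config$mode == "controlled_rotation") {
    deg_per_frame <- config$rotation_speed * 360 / 60 / fr
    n_rot <- round(config$rotation_duration * fr)
    n_rest <- round(config$rest_duration * fr)
    heading_u <- numeric(0)   # unwrapped
    light <- logical(0)
    rest <- logical(0)
    cur <- stats::runif(1, 0, 360)  # random starting orientation
    for (r in seq_len(config$n_repeats)) {
      step <- deg_per_frame *
        pmax(1 + stats::rnorm(n_rot, 0, config$rotation_jitter), 0.5)
      block <- cur + cumsum(step)
      heading_u <- c(heading_u, block)
      light <- c(light, rep(config$light_schedule[r] == "on", n_rot))
      rest <- c(rest, rep(FALSE, n_rot))
      cur <- block[n_rot]
      if (r < config$n_repeats && n_rest > 0L) {
        heading_u <- c(heading_u, rep(cur, n_rest))
        # lights switch mid-rest, so the transition never falls inside a trial
        half <- n_rest %/% 2L
        next_on <- config$light_schedule[r + 1L] == "on"
        light <- c(light, rep(config$light_schedule[r] == "on", half),
                   rep(next_on, n_rest - half))
        rest <- c(rest, rep(TRUE, n_rest))
      }
    }
    n <- length(heading_u)
    # trial = completed full rotation within a repeat
    trial_id <- rep(NA_integer_, n)
    ntrial <- 0L
    i <- 1L
    while (i <= n) {
      if (rest[i]) { i <- i + 1L; next }
      j <- i
      while (j <= n && !rest[j]) j <- j + 1L   # rotation block [i, j-1]
      prog <- heading_u[i:(j - 1L)] - heading_u[i]
      # a sweep is complete once every heading bin has been visited, i.e. it
      # spans 360 degrees up to one frame step
      full <- floor((max(prog) + deg_per_frame) / 360 + 1e-9)
      if (full >= 1L) {
        idx_trial <- pmin(floor(prog / 360), full - 1L)  # leftover -> NA below
        keep <- prog < full * 360
        ids <- rep(NA_integer_, length(prog))
        ids[keep] <- ntrial + idx_trial[keep] + 1L
        trial_id[i:(j - 1L)] <- ids
        ntrial <- ntrial + full
      }
      i <- j
    }
    out <- data.frame(
      t = (seq_len(n) - 1L) * dt,
      x = 0, y = 0, speed = 0,
      heading = wrap360(heading_u),
      light_on = light,
      trial_id = trial_id,
      is_rest = rest)
  } else {
    n <- round(config$duration * fr)
    dh <- numeric(n)
    sd_step <- 20 * dt * 10  # degrees per frame scale before persistence
    for (k in 2:n) dh[k] <- config$persistence * dh[k - 1] +
      stats::rnorm(1, 0, sd_step * (1 - config$persistence))
    heading_u <- stats::runif(1, 0, 360) + cumsum(dh)
    pos <- matrix(0, n, 2)
    step <- matrix(stats::rnorm(2 * n, 0, 5 * dt * 10), n, 2)
    for (k in 2:n) {
      p <- pos[k - 1, ] + step[k, ]
      if (sqrt(sum(p^2)) > 150) p <- pos[k - 1, ] - step[k, ]
      pos[k, ] <- p
    }
    spd <- c(0, sqrt(rowSums(diff(pos)^2))) / dt
    out <- data.frame(
      t = (seq_len(n) - 1L) * dt,
      x = pos[, 1], y = pos[, 2], speed = spd,
      heading = wrap360(heading_u),
      light_on = TRUE,
      trial_id = NA_integer_,
      is_rest = FALSE)
  }
  attr(out, "frame_rate") <- fr
  attr(out, "config") <- config
  class(out) <- c("tracking_series", "data.frame")
  out
}

#' @export
print.tracking_series <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("tracking_series: %d frames at %g Hz (%s)\n",
              nrow(x), attr(x, "frame_rate"),
              if (is.null(cfg)) "unknown mode" else cfg$mode))
  nt <- length(unique(stats::na.omit(x$trial_id)))
  cat(sprintf("  %d full-rotation trials; %d rest frames; light on %.0f%% of frames\n",
              nt, sum(x$is_rest), 100 * mean(x$light_on)))
  invisible(x)
}

#' Per-trial light condition of a tracking series
#'
#' @param track a `tracking_series`.
#' @return named logical vector, TRUE for light-on, indexed by trial id.
#' @export
trial_light <- function(track) {
  ids <- sort(unique(stats::na.omit(track$trial_id)))
  out <- vapply(ids, function(id) {
    all(track$light_on[!is.na(track$trial_id) & track$trial_id == id])
  }, logical(1))
  # a trial straddling a light switch would be ambiguous; the generator
  # guarantees switches happen during rests, so `all` equals `any` here
  names(out) <- ids
  out
}
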