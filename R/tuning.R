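#' @keywords internal
bin_centers_deg <- function(n_bins = 60) (seq_len(n_bins) - 0.5) * 360 / n_bins

# circular boxcar smoothing of a curve; width in bins (odd)
smooth_circular <- function(x, width = 3L) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half <- (width - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, function(i, k) ((i + k - 1L) %% n) + 1L)
  if (anyNA(x)) {
    apply(idx, 1, function(j) mean(x[j], na.rm = TRUE))
  } else {
    rowMeans(matrix(x[idx], n))
  }
}

#' Heading tuning curve of one cell
#'
#' Bins a spike series by chamber heading into 60 bins of 6 degrees, builds a
#' per-trial spike-rate curve for every full-rotation trial (each smoothed by
#' a circular moving-average filter of ~15 degrees, implemented as a 3-bin
#' window), and averages across trials. Rest frames and frames outside full
#' rotations are excluded. Heading bins a trial never visits are marked
#' missing and excluded from the trial average.
#'
#' @param spikes numeric spike series (one cell), aligned frame-wise to
#'   `track`.
#' @param track a [generate_session()] tracking series.
#' @param condition `"all"`, `"light_on"` or `"light_off"`: which trials to
#'   include.
#' @param n_bins number of heading bins (default 60).
#' @param smooth_bins circular moving-average width in bins (odd; default 3,
#'   i.e. 18 degrees on the 6-degree grid — the closest odd-width realisation
#'   of a 15-degree filter).
#' @return object of class `tuning_curve`: `bin_centers`, `per_trial`
#'   (trials x bins rate matrix, smoothed), `mean_curve`, `condition`,
#'   `trial_ids`.
#' @export
tuning_curve <- function(spikes, track, condition = c("all", "light_on", "light_off"),
                         n_bins = 60L, smooth_bins = 3L) {
  condition <- match.arg(condition)
  stopifnot(length(spikes) == nrow(track))
  fr <- attr(track, "frame_rate")
  tl <- trial_light(track)
  ids <- as.integer(names(tl))
  use <- switch(condition, all = ids, light_on = ids[tl], light_off = ids[!tl])
  bins <- findInterval(wrap360(track$heading), seq(0, 360, by = 360 / n_bins),
                       rightmost.closed = TRUE)
  bins[bins > n_bins] <- n_bins
  per_trial <- matrix(NA_real_, length(use), n_bins)
  for (k in seq_along(use)) {
    sel <- !is.na(track$trial_id) & track$trial_id == use[k]
    cnt <- tapply(spikes[sel], factor(bins[sel], levels = seq_len(n_bins)), sum)
    occ <- tabulate(bins[sel], n_bins)
    rate <- rep(NA_real_, n_bins)
    vis <- occ > 0
    rate[vis] <- as.numeric(cnt[vis]) / (occ[vis] / fr)
    per_trial[k, ] <- smooth_circular(rate, smooth_bins)
  }
  mean_curve <- if (nrow(per_trial)) colMeans(per_trial, na.rm = TRUE)
                else rep(NA_real_, n_bins)
  mean_curve[is.nan(mean_curve)] <- NA_real_
  structure(list(bin_centers = bin_centers_deg(n_bins), per_trial = per_trial,
                 mean_curve = mean_curve, condition = condition,
                 trial_ids = use),
            class = "tuning_curve")
}

#' Tuning curves for a population
#'
#' @param spikes cells x frames matrix.
#' @param track tracking series.
#' @param ... passed to [tuning_curve()].
#' @return list of `tuning_curve` objects, one per row of `spikes`.
#' @export
compute_tuning_curves <- function(spikes, track, ...) {
  lapply(seq_len(nrow(spikes)), function(i) tuning_curve(spikes[i, ], track, ...))
}

#' Preferred direction of a tuning curve
#'
#' Argmax of the (already smoothed) mean curve, refined below the bin width
#' by parabolic interpolation through the peak bin and its two circular
#' neighbours (the standard sub-bin peak estimate); exact ties are broken by
#' the circular mean of the tied bin centres.
#'
#' @param curve a `tuning_curve` or a plain numeric curve.
#' @return preferred direction in degrees.
#' @export
preferred_direction <- function(curve) {
  y <- if (inherits(curve, "tuning_curve")) curve$mean_curve else curve
  bc <- if (inherits(curve, "tuning_curve")) curve$bin_centers
        else bin_centers_deg(length(y))
  if (all(is.na(y))) return(NA_real_)
  top <- which(y >= max(y, na.rm = TRUE) - 1e-12)
  if (length(top) > 1L) return(circ_mean(bc[top]))
  n <- length(y)
  w <- 360 / n
  i0 <- top
  yl <- y[((i0 - 2) %% n) + 1]; y0 <- y[i0]; yr <- y[(i0 %% n) + 1]
  if (is.na(yl) || is.na(yr)) return(bc[i0])
  denom <- yl - 2 * y0 + yr
  shift <- if (abs(denom) < .Machine$double.eps) 0
           else max(-0.5, min(0.5, 0.5 * (yl - yr) / denom))
  wrap360(bc[i0] + shift * w)
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("tuning_curve (%s): %d trials x %d bins; peak %.0f deg, rate %.2f\n",
              x$condition, nrow(x$per_trial), length(x$mean_curve),
              preferred_direction(x), max(x$mean_curve, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::matplot(x$bin_centers, t(x$per_trial), type = "l", lty = 1,
                    col = grDevices::grey(0.8), xlab = "heading (deg)",
                    ylab = "rate (spikes/s)", ...)
  graphics::lines(x$bin_centers, x$mean_curve, lwd = 2)
  invisible(x)
}

#' Cross-validated alignment of per-trial tuning curves
#'
#' For each trial, the mean of the remaining trials defines a reference
#' tuning curve whose peak bin is used to rotate the held-out trial so that
#' its estimated peak lands on a common reference bin. When a companion
#' matrix is supplied (e.g. the same cell's light-off trial curves, which
#' need not have the same number of trials), every companion row is rotated
#' by the cell's overall offset (reference bin minus the peak of the full
#' mean curve), so both conditions share one circular offset derived from
#' the aligning condition.
#'
#' @param per_trial trials x bins matrix (>= 2 trials).
#' @param companion optional matrix with the same number of bins to
#'   co-rotate.
#' @param ref_bin reference bin index the peaks are rotated to (default the
#'   middle bin).
#' @return list with `aligned`, `companion_aligned` (or NULL), `offsets`
#'   (bins each trial was shifted by), `overall_offset` (bins, applied to
#'   the companion), `flagged` (all-zero trials or degenerate references;
#'   such trials are left unshifted).
#' @export
crossval_align <- function(per_trial, companion = NULL,
                           ref_bin = ncol(per_trial) %/% 2L + 1L) {
  n_tr <- nrow(per_trial); n_bins <- ncol(per_trial)
  if (n_tr < 2L) stop("cross-validated alignment needs at least 2 trials")
  if (!is.null(companion)) stopifnot(ncol(companion) == n_bins)
  aligned <- per_trial
  offsets <- integer(n_tr)
  flagged <- logical(n_tr)
  for (i in seq_len(n_tr)) {
    if (all(per_trial[i, ] == 0, na.rm = TRUE)) flagged[i] <- TRUE
    ref <- colMeans(per_trial[-i, , drop = FALSE], na.rm = TRUE)
    if (all(is.na(ref)) ||
        isTRUE(all.equal(stats::var(ref[!is.na(ref)]), 0))) {
      flagged[i] <- TRUE
      next
    }
    k <- ref_bin - which.max(ref)
    offsets[i] <- k
    aligned[i, ] <- circ_shift(per_trial[i, ], k)
  }
  full <- colMeans(per_trial, na.rm = TRUE)
  overall <- if (all(is.na(full)) ||
                 isTRUE(all.equal(stats::var(full[!is.na(full)]), 0))) 0L
             else ref_bin - which.max(full)
  comp_al <- NULL
  if (!is.null(companion)) {
    comp_al <- companion
    for (i in seq_len(nrow(companion)))
      comp_al[i, ] <- circ_shift(companion[i, ], overall)
  }
  list(aligned = aligned, companion_aligned = comp_al,
       offsets = offsets, overall_offset = overall, flagged = flagged)
}
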