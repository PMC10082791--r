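#' Rayleigh-vector heading selectivity (shuffle test)
#'
#' Used for voluntary (floating-chamber) sessions: the Rayleigh vector length
#' (RVL) of the cell's heading tuning curve is compared against a null
#' distribution obtained by circularly shifting the spike series by random
#' lags and recomputing the RVL each time. The cell is selective when the
#' true RVL meets or exceeds the chosen percentile of the shuffles.
#'
#' The time-shift shuffle assumes an irregular heading trajectory; under
#' strictly periodic controlled rotation a time shift preserves tuning and
#' the test loses power by construction, which is why rotation sessions use
#' [trialwise_selectivity()] instead.
#'
#' @param spikes spike series of one cell.
#' @param heading per-frame heading in degrees, same length.
#' @param n_shuffles number of circular-shift shuffles (default 1000).
#' @param percentile shuffle percentile the true RVL must reach (default 99).
#' @param n_bins heading bins (default 60).
#' @param min_shift_frames minimum shuffle lag, to break local correlation
#'   (default 1 s worth at 10 Hz).
#' @return list of class `selectivity_result`: `rvl`, `rvl_percentile`
#'   (percentile of the true RVL within the shuffles), `selective`,
#'   `preferred_deg`, `undefined` (TRUE when the cell fired no spikes).
#' @export
rvl_selectivity <- function(spikes, heading, n_shuffles = 1000, percentile = 99,
                            n_bins = 60L, min_shift_frames = 10L) {
  stopifnot(length(spikes) == length(heading))
  n <- length(spikes)
  if (sum(spikes) <= 0) {
    return(structure(list(rvl = NA_real_, rvl_percentile = NA_real_,
                          selective = FALSE, preferred_deg = NA_real_,
                          undefined = TRUE), class = "selectivity_result"))
  }
  if (stats::sd(spikes) == 0) {
    # a constant series is invariant under circular shifts: the shuffle
    # distribution degenerates to the true value, so no evidence of tuning
    return(structure(list(rvl = NA_real_, rvl_percentile = NA_real_,
                          selective = FALSE, preferred_deg = NA_real_,
                          undefined = TRUE), class = "selectivity_result"))
  }
  bins <- findInterval(wrap360(heading), seq(0, 360, by = 360 / n_bins),
                       rightmost.closed = TRUE)
  bins[bins > n_bins] <- n_bins
  occ <- tabulate(bins, n_bins)
  fbins <- factor(bins, levels = seq_len(n_bins))
  curve_of <- function(s) {
    cnt <- vapply(split(s, fbins), sum, numeric(1), USE.NAMES = FALSE)
    ifelse(occ > 0, cnt / occ, 0)
  }
  rvl_of <- function(curve) rayleigh_vector_length(bin_centers_deg(n_bins), curve)
  real_curve <- curve_of(spikes)
  real <- rvl_of(real_curve)
  lo <- min(min_shift_frames, n - 1L)
  lags <- sample(seq.int(lo, n - lo), n_shuffles, replace = TRUE)
  null <- vapply(lags, function(k) rvl_of(curve_of(circ_shift(spikes, k))),
                 numeric(1))
  thr <- stats::quantile(null, percentile / 100, names = FALSE)
  structure(list(rvl = real,
                 rvl_percentile = 100 * mean(null < real),
                 selective = real >= thr,
                 preferred_deg = preferred_direction(real_curve),
                 undefined = FALSE),
            class = "selectivity_result")
}

# random circular shift of every row of a per-trial matrix
shift_rows <- function(m, lags) {
  n_bins <- ncol(m)
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- circ_shift(m[i, ], lags[i])
  out
}

# correlations between paired rows of two matrices (NAs poisoned upstream)
rowwise_cor <- function(M1, M2) {
  M1 <- M1 - rowMeans(M1); M2 <- M2 - rowMeans(M2)
  v <- rowSums(M1^2) * rowSums(M2^2)
  r <- rep(0, nrow(M1))
  ok <- v > 0
  r[ok] <- rowSums(M1 * M2)[ok] / sqrt(v[ok])
  r
}

# n_rep x n_tr 0/1 indicators of random half-splits (TRUE = first half)
random_splits <- function(n_rep, n_tr) {
  half <- n_tr %/% 2L
  t(vapply(seq_len(n_rep), function(r) {
    g <- logical(n_tr); g[sample.int(n_tr, half)] <- TRUE; g
  }, logical(n_tr)))
}

# split-half correlations for n_rep random splits of a fixed trial matrix
split_cors <- function(P, G1) {
  M1 <- (G1 %*% P) / rowSums(G1)
  M2 <- ((!G1) %*% P) / rowSums(!G1)
  rowwise_cor(M1, M2)
}

# split-half correlations where each trial row is independently circularly
# shifted per repetition; lags is n_rep x n_tr
shifted_split_cors <- function(P, G1, lags) {
  n_rep <- nrow(G1); n_tr <- nrow(P); n_bins <- ncol(P)
  M1 <- matrix(0, n_rep, n_bins)
  M2 <- matrix(0, n_rep, n_bins)
  base <- seq_len(n_bins)
  for (t in seq_len(n_tr)) {
    # row t shifted by each repetition's lag: index magic instead of loops
    idx <- outer(lags[, t], base, function(k, j) ((j - k - 1L) %% n_bins) + 1L)
    V <- matrix(P[t, idx], n_rep, n_bins)
    M1 <- M1 + G1[, t] * V
    M2 <- M2 + (!G1[, t]) * V
  }
  rowwise_cor(M1 / rowSums(G1), M2 / rowSums(!G1))
}

# mean curves of independently shifted trial matrices, one per repetition
shifted_mean_curves <- function(P, lags) {
  n_rep <- nrow(lags); n_tr <- nrow(P); n_bins <- ncol(P)
  M <- matrix(0, n_rep, n_bins)
  base <- seq_len(n_bins)
  for (t in seq_len(n_tr)) {
    idx <- outer(lags[, t], base, function(k, j) ((j - k - 1L) %% n_bins) + 1L)
    M <- M + matrix(P[t, idx], n_rep, n_bins)
  }
  M / n_tr
}

#' Trial-reliability heading selectivity for rotation sessions
#'
#' Combines three criteria into one verdict:
#' \enumerate{
#'   \item Split-half reliability: trials are randomly split in two and the
#'     correlation between the two half tuning curves is computed; repeating
#'     this gives the "real" distribution. A null distribution is built the
#'     same way after circularly shifting each trial's curve by a random lag.
#'     The two distributions are compared with a two-sample
#'     Kolmogorov-Smirnov test (must pass at `ks_p < ks_alpha`) and with
#'     Cohen's d (pooled-SD standardised mean difference, must exceed
#'     `d_threshold`).
#'   \item Tuning shape: a one-term (single cue) or two-term (dual cue)
#'     Gaussian is fit to the trial-averaged curve; its r-squared must exceed
#'     the `r2_percentile`-th percentile of r-squared values from fits to
#'     shuffled trial-averaged curves.
#' }
#' All inequalities are strict. Because the verdict is a conjunction, the
#' (expensive) Gaussian stage is skipped by default when the reliability
#' stage already failed (`fit_stage = "auto"`).
#'
#' @param per_trial trials x bins smoothed rate matrix (>= 4 trials), e.g.
#'   `tuning_curve(...)$per_trial`.
#' @param n_shuffles repetitions for splits and shuffles (default 1000).
#' @param n_terms Gaussian terms: 1 for single-cue, 2 for dual-cue sessions.
#' @param ks_alpha KS threshold (default 0.1).
#' @param d_threshold Cohen's d threshold (default 0.8).
#' @param r2_percentile shuffle percentile for the r-squared criterion
#'   (default 90).
#' @param fit_stage `"auto"` (skip Gaussian stage when reliability already
#'   failed) or `"always"`.
#' @return list of class `selectivity_result`: `ks_p`, `cohens_d`, `r2_real`,
#'   `r2_shuffle_q90`, `selective`, `preferred_deg`.
#' @export
trialwise_selectivity <- function(per_trial, n_shuffles = 1000, n_terms = 2,
                                  ks_alpha = 0.1, d_threshold = 0.8,
                                  r2_percentile = 90,
                                  fit_stage = c("auto", "always")) {
  fit_stage <- match.arg(fit_stage)
  n_tr <- nrow(per_trial); n_bins <- ncol(per_trial)
  if (n_tr < 4L) stop("trial-based selectivity requires at least 4 trials")
  P <- per_trial
  if (anyNA(P)) {
    # missing bins (never visited within a trial): fill with the trial mean
    # so split and shuffle machinery stays exact-shape; rare in rotation data
    for (i in seq_len(n_tr)) {
      bad <- is.na(P[i, ])
      if (any(bad)) P[i, bad] <- mean(P[i, !bad])
    }
  }
  real <- split_cors(P, random_splits(n_shuffles, n_tr))
  null <- shifted_split_cors(P, random_splits(n_shuffles, n_tr),
                             matrix(sample.int(n_bins - 1L, n_shuffles * n_tr,
                                               replace = TRUE),
                                    n_shuffles, n_tr))
  ks_p <- suppressWarnings(stats::ks.test(real, null)$p.value)
  sp <- sqrt(((length(real) - 1) * stats::var(real) +
              (length(null) - 1) * stats::var(null)) /
             (length(real) + length(null) - 2))
  cohens_d <- if (sp > 0) (mean(real) - mean(null)) / sp else 0
  mean_curve <- colMeans(per_trial, na.rm = TRUE)
  reliable <- ks_p < ks_alpha && cohens_d > d_threshold
  r2_real <- r2_q <- NA_real_
  shaped <- FALSE
  if (reliable || fit_stage == "always") {
    r2_real <- fit_sum_of_gaussians(mean_curve, n_terms = n_terms)$r2
    shuf <- shifted_mean_curves(P, matrix(sample.int(n_bins - 1L,
                                                     n_shuffles * n_tr,
                                                     replace = TRUE),
                                          n_shuffles, n_tr))
    # sequential shortcut: once enough shuffle fits reach r2_real, the full
    # shuffle quantile is guaranteed to sit at or above it, so the verdict
    # is already decided and the remaining fits are skipped
    k_rank <- floor(1 + (r2_percentile / 100) * (n_shuffles - 1))
    e_stop <- n_shuffles - k_rank + 1L
    r2_null <- rep(NA_real_, n_shuffles)
    exceed <- 0L
    for (r in seq_len(n_shuffles)) {
      r2_null[r] <- fit_sum_of_gaussians(shuf[r, ], n_terms = n_terms)$r2
      if (!is.na(r2_real) && !is.na(r2_null[r]) && r2_null[r] >= r2_real) {
        exceed <- exceed + 1L
        if (exceed >= e_stop) break
      }
    }
    used <- !is.na(r2_null)
    r2_q <- stats::quantile(r2_null[used], r2_percentile / 100, names = FALSE)
    shaped <- sum(used) == n_shuffles && !is.na(r2_real) && r2_real > r2_q
  }
  structure(list(ks_p = ks_p, cohens_d = cohens_d, r2_real = r2_real,
                 r2_shuffle_q90 = r2_q, selective = reliable && shaped,
                 preferred_deg = preferred_direction(mean_curve)),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat("selectivity_result:", if (isTRUE(x$selective)) "selective" else "not selective", "\n")
  f <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.3g", v)
  if (!is.null(x$rvl)) cat("  RVL", f(x$rvl), "at shuffle percentile", f(x$rvl_percentile), "\n")
  if (!is.null(x$ks_p)) cat("  KS p", f(x$ks_p), "| Cohen's d", f(x$cohens_d),
                            "| r2", f(x$r2_real), "vs shuffle q90", f(x$r2_shuffle_q90), "\n")
  cat("  preferred direction:", f(x$preferred_deg), "deg\n")
  invisible(x)
}

#' Per-cell selectivity table for a population
#'
#' Runs the trial-based test (rotation sessions) on every cell and collects
#' the statistics into one data frame, suitable for writing as TSV.
#'
#' @param curves list of `tuning_curve` objects (one per cell).
#' @param n_shuffles,n_terms,... passed to [trialwise_selectivity()].
#' @return data frame with one row per cell.
#' @export
selectivity_table <- function(curves, n_shuffles = 1000, n_terms = 2, ...) {
  rows <- lapply(seq_along(curves), function(i) {
    s <- trialwise_selectivity(curves[[i]]$per_trial, n_shuffles = n_shuffles,
                               n_terms = n_terms, ...)
    data.frame(cell_id = i, test_used = "trialwise", ks_p = s$ks_p,
               cohens_d = s$cohens_d, r2_real = s$r2_real,
               r2_q90 = s$r2_shuffle_q90, selective = s$selective,
               preferred_deg = s$preferred_deg)
  })
  do.call(rbind, rows)
}
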