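#' Resample trials onto a common 200-bin grid
#'
#' Every full-rotation trial is linearly interpolated to exactly `n_out`
#' time bins. Activity is interpolated directly; heading is unwrapped to a
#' continuous angle before interpolation and re-wrapped to [0, 360), so the
#' 359 -> 1 degree crossing produces no artifact. Trials that do not span a
#' full rotation (at least `min_span` degrees, the slack allowing for the
#' half-open frame grid) are excluded with a warning.
#'
#' @param activity cells x frames matrix (inferred spikes or dF/F).
#' @param track tracking series aligned to `activity`.
#' @param n_out output bins per trial (default 200).
#' @param min_span minimum heading span for a trial to count as a full
#'   rotation, degrees (default 350).
#' @return list of class `aligned_trials`: `activity` (cells x trials x
#'   n_out array), `heading` (trials x n_out), `light_on` (per trial),
#'   `trial_ids`.
#' @export
resample_trials <- function(activity, track, n_out = 200L, min_span = 350) {
  stopifnot(ncol(activity) == nrow(track))
  tl <- trial_light(track)
  ids <- as.integer(names(tl))
  keep <- logical(length(ids))
  act_list <- vector("list", length(ids))
  head_list <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sel <- which(!is.na(track$trial_id) & track$trial_id == ids[k])
    hu <- unwrap_deg(track$heading[sel])
    span <- abs(hu[length(hu)] - hu[1])
    if (span < min_span) {
      warning(sprintf("trial %d spans only %.0f degrees; excluded", ids[k], span))
      next
    }
    keep[k] <- TRUE
    xin <- seq(0, 1, length.out = length(sel))
    xout <- seq(0, 1, length.out = n_out)
    head_list[[k]] <- wrap360(stats::approx(xin, hu, xout)$y)
    act_list[[k]] <- t(apply(activity[, sel, drop = FALSE], 1, function(a)
      stats::approx(xin, a, xout)$y))
  }
  if (!any(keep)) stop("no full-rotation trials found")
  kept <- which(keep)
  arr <- array(0, dim = c(nrow(activity), length(kept), n_out))
  hd <- matrix(0, length(kept), n_out)
  for (k in seq_along(kept)) {
    arr[, k, ] <- act_list[[kept[k]]]
    hd[k, ] <- head_list[[kept[k]]]
  }
  structure(list(activity = arr, heading = hd,
                 light_on = unname(tl[kept]), trial_ids = ids[kept]),
            class = "aligned_trials")
}

#' @export
print.aligned_trials <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("aligned_trials: %d cells x %d trials x %d bins (%d light-on trials)\n",
              d[1], d[2], d[3], sum(x$light_on)))
  invisible(x)
}

#' Subset an aligned-trials object
#' @param aligned an `aligned_trials` object.
#' @param cells,trials index vectors (cells may repeat, for bootstrap draws).
#' @return an `aligned_trials` object.
#' @export
subset_aligned <- function(aligned, cells = NULL, trials = NULL) {
  if (is.null(cells)) cells <- seq_len(dim(aligned$activity)[1])
  if (is.null(trials)) trials <- seq_len(dim(aligned$activity)[2])
  structure(list(activity = aligned$activity[cells, trials, , drop = FALSE],
                 heading = aligned$heading[trials, , drop = FALSE],
                 light_on = aligned$light_on[trials],
                 trial_ids = aligned$trial_ids[trials]),
            class = "aligned_trials")
}

#' Bootstrap pseudopopulation samples
#'
#' Draws cell indices for decoding iterations. With a single class filter,
#' each iteration samples (with replacement) `n_sample` cells of that class,
#' where `n_sample` defaults to the size of the smallest class present (so
#' every class is decoded with equally sized populations). With
#' `class_filter = "all_tuned"`, cells are drawn from all tuned classes
#' jointly, preserving their empirical proportions.
#'
#' @param labels per-cell class labels.
#' @param class_filter one of the class names or `"all_tuned"`.
#' @param n_boot number of bootstrap iterations.
#' @param n_sample cells per draw; default min class size among
#'   heading/landmark/alignment.
#' @param classes tuned class names.
#' @param seed integer seed.
#' @return list of integer index vectors, one per iteration.
#' @export
build_pseudopopulation <- function(labels, class_filter = "all_tuned",
                                   n_boot = 1000,
                                   n_sample = NULL,
                                   classes = c("heading", "landmark", "alignment"),
                                   seed = 1L) {
  set.seed(seed)
  sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  present <- sizes > 0
  if (!any(present)) stop("no tuned cells available")
  if (is.null(n_sample)) n_sample <- min(sizes[present])
  if (class_filter == "all_tuned") {
    pool <- which(labels %in% classes)
  } else {
    if (!class_filter %in% classes) stop("unknown class filter: ", class_filter)
    pool <- which(labels == class_filter)
    if (length(pool) == 0L) stop("empty class: ", class_filter)
  }
  lapply(seq_len(n_boot), function(b) sample(pool, n_sample, replace = TRUE))
}

#' Naive Bayes heading decoder with an even/odd split
#'
#' Flattens all trial time bins, assigns even time-bin indices to training
#' and odd indices to testing, estimates a per-cell activity model in each of
#' `n_bins` heading bins from the training data, and decodes every test frame
#' as the maximum-posterior heading bin under a uniform prior. The default
#' likelihood treats activity as Poisson counts (appropriate for inferred
#' spikes); a Gaussian likelihood on continuous traces is available for
#' parity checks. Heading bins never visited in training are excluded from
#' the decodable states with a warning. Only test frames are reported.
#'
#' @param aligned an `aligned_trials` object (possibly subset to one class
#'   and/or condition).
#' @param n_bins heading bins for the decoder state space (default 60).
#' @param likelihood `"poisson"` or `"gaussian"`.
#' @return object of class `decode_result` (see [decoder_metrics()]) with
#'   per-test-frame `decoded`, `actual`, `trial`, `light_on` plus the metric
#'   fields.
#' @export
decode_bayes <- function(aligned, n_bins = 60L,
                         likelihood = c("poisson", "gaussian")) {
  likelihood <- match.arg(likelihood)
  d <- dim(aligned$activity)
  n_cells <- d[1]; n_tr <- d[2]; n_t <- d[3]
  if (n_tr < 2L) stop("decoding needs at least 2 trials")
  if (min(aligned$activity) < 0) stop("activity must be nonnegative")
  act <- matrix(aligned$activity, n_cells, n_tr * n_t)  # col = (trial, time)
  hd <- as.vector(aligned$heading)                      # same (trial, time) order
  trial_of <- rep(seq_len(n_tr), times = n_t)
  time_of <- rep(seq_len(n_t), each = n_tr)
  train <- time_of %% 2L == 0L
  test <- !train
  hbin <- findInterval(wrap360(hd), seq(0, 360, by = 360 / n_bins),
                       rightmost.closed = TRUE)
  hbin[hbin > n_bins] <- n_bins
  occ <- tabulate(hbin[train], n_bins)
  usable <- which(occ > 0)
  if (length(usable) < n_bins)
    warning(sprintf("%d heading bins unvisited in training; excluded",
                    n_bins - length(usable)))
  # per-bin mean activity from training frames
  mu <- matrix(0, n_cells, length(usable))
  for (j in seq_along(usable)) {
    cols <- train & hbin == usable[j]
    mu[, j] <- rowMeans(act[, cols, drop = FALSE])
  }
  X <- act[, test, drop = FALSE]
  if (likelihood == "poisson") {
    lam <- pmax(mu, 1e-6)
    LL <- crossprod(log(lam), X) - colSums(lam)   # bins x test frames
  } else {
    s <- apply(act[, train, drop = FALSE], 1, stats::sd)
    s <- pmax(s, 1e-6)
    LL <- -0.5 * (crossprod((mu / s)^2, matrix(1, n_cells, ncol(X))) -
                  2 * crossprod(mu / s^2, X))
  }
  best <- apply(LL, 2, which.max)
  decoded <- bin_centers_deg(n_bins)[usable[best]]
  res <- decoder_metrics(decoded, hd[test], trial = trial_of[test])
  res$light_on <- aligned$light_on[trial_of[test]]
  res$likelihood <- likelihood
  res
}

#' Decoder error and accuracy
#'
#' Error is the absolute circular difference between decoded and actual
#' heading (degrees in [0, 180]). Accuracy is the fraction of frames whose
#' error is below the 18-degree window, computed per trial; chance level is
#' 0.10 (= 36/360, the probability a uniformly random decode lands within
#' +/- 18 degrees of the truth).
#'
#' @param decoded,actual headings in degrees, equal length.
#' @param trial optional per-frame trial ids (default: one trial).
#' @param window accuracy window in degrees (default 18).
#' @return object of class `decode_result`: `decoded`, `actual`, `trial`,
#'   `error`, `accuracy_per_trial`, `accuracy` (mean of per-trial
#'   accuracies), `window`.
#' @export
decoder_metrics <- function(decoded, actual, trial = NULL, window = 18) {
  stopifnot(length(decoded) == length(actual))
  if (length(decoded) == 0L) stop("empty trial: no frames to score")
  if (is.null(trial)) trial <- rep(1L, length(decoded))
  err <- circ_dist(decoded, actual)
  acc_tr <- tapply(err < window, trial, mean)
  structure(list(decoded = decoded, actual = actual, trial = trial,
                 error = err,
                 accuracy_per_trial = as.numeric(acc_tr),
                 accuracy = mean(as.numeric(acc_tr)),
                 window = window),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: %d test frames, %d trials\n",
              length(x$decoded), length(unique(x$trial))))
  cat(sprintf("  median error %.1f deg; accuracy %.3f (window %g deg, chance 0.10)\n",
              stats::median(x$error), x$accuracy, x$window))
  invisible(x)
}

#' Summarise a bootstrap distribution of decoder accuracies
#'
#' @param accuracies per-iteration accuracies (>= 2).
#' @param chance chance accuracy level (default 0.10).
#' @param ci_level percentile CI coverage (default 0.95 -> 2.5th/97.5th
#'   percentiles).
#' @return list with `mean`, `ci_low`, `ci_high`, `chance`, `significant`
#'   (CI excludes chance), `median_iteration` (index of the iteration with
#'   median performance, for representative plotting).
#' @export
bootstrap_accuracy <- function(accuracies, chance = 0.10, ci_level = 0.95) {
  if (length(accuracies) < 2L) stop("need at least 2 bootstrap iterations")
  a <- (1 - ci_level) / 2
  ci <- stats::quantile(accuracies, c(a, 1 - a), names = FALSE)
  list(mean = mean(accuracies), ci_low = ci[1], ci_high = ci[2],
       chance = chance, significant = chance < ci[1] || chance > ci[2],
       median_iteration = which.min(abs(accuracies - stats::median(accuracies))))
}

#' Class-wise pseudopopulation decoding
#'
#' For each bootstrap iteration, samples a pseudopopulation of the requested
#' class, decodes heading with [decode_bayes()] (training on even time bins
#' across both light conditions), and scores accuracy separately on light-on
#' and light-off test frames.
#'
#' @param aligned an `aligned_trials` object containing light-on and
#'   light-off trials.
#' @param labels per-cell class labels.
#' @param class_filter class name or `"all_tuned"`.
#' @param n_boot bootstrap iterations.
#' @param n_sample cells per iteration (default: smallest class size).
#' @param likelihood decoder likelihood.
#' @param seed integer seed.
#' @return list of class `population_decoding`: `accuracy_on`,
#'   `accuracy_off` (per-iteration vectors), `summary_on`, `summary_off`
#'   (from [bootstrap_accuracy()]), `class_filter`, `n_sample`.
#' @export
decode_population <- function(aligned, labels, class_filter = "all_tuned",
                              n_boot = 100, n_sample = NULL,
                              likelihood = "poisson", seed = 1L) {
  draws <- build_pseudopopulation(labels, class_filter = class_filter,
                                  n_boot = n_boot, n_sample = n_sample,
                                  seed = seed)
  acc_on <- acc_off <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    res <- decode_bayes(subset_aligned(aligned, cells = draws[[b]]),
                        likelihood = likelihood)
    per_tr <- tapply(res$error < res$window, res$trial, mean)
    tr_light <- tapply(res$light_on, res$trial, function(v) v[1])
    acc_on[b] <- mean(per_tr[tr_light])
    acc_off[b] <- if (any(!tr_light)) mean(per_tr[!tr_light]) else NA_real_
  }
  structure(list(accuracy_on = acc_on, accuracy_off = acc_off,
                 summary_on = bootstrap_accuracy(acc_on),
                 summary_off = if (all(is.na(acc_off))) NULL
                               else bootstrap_accuracy(acc_off[!is.na(acc_off)]),
                 class_filter = class_filter,
                 n_sample = length(draws[[1]])),
            class = "population_decoding")
}

#' @export
print.population_decoding <- function(x, ...) {
  cat(sprintf("population_decoding (%s, %d cells/draw, %d iterations)\n",
              x$class_filter, x$n_sample, length(x$accuracy_on)))
  s <- x$summary_on
  cat(sprintf("  light-on : accuracy %.2f [%.2f, %.2f]\n",
              s$mean, s$ci_low, s$ci_high))
  if (!is.null(x$summary_off)) {
    s <- x$summary_off
    cat(sprintf("  light-off: accuracy %.2f [%.2f, %.2f] (chance %.2f)\n",
                s$mean, s$ci_low, s$ci_high, s$chance))
  }
  invisible(x)
}
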