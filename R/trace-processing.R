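#' Neuropil correction of a somatic fluorescence trace
#'
#' Subtracts the scaled, mean-centred neuropil signal from the somatic signal:
#' `F_corrected = F_soma - alpha * (F_neuropil - mean(F_neuropil))`, where
#' `alpha` is chosen from [0, 1] to minimise the absolute Pearson correlation
#' between the corrected trace and the neuropil trace (golden-section search).
#'
#' @param F_soma,F_neuropil numeric vectors of equal length.
#' @return list with `F_corrected`, `alpha`, and `degenerate` (TRUE when the
#'   neuropil trace is constant, in which case `alpha = 0` with a warning).
#' @export
neuropil_correct <- function(F_soma, F_neuropil) {
  stopifnot(length(F_soma) == length(F_neuropil))
  np_c <- F_neuropil - mean(F_neuropil)
  if (stats::sd(F_neuropil) < .Machine$double.eps^0.5 ||
      stats::sd(F_soma) < .Machine$double.eps^0.5) {
    if (stats::sd(F_neuropil) < .Machine$double.eps^0.5)
      warning("constant neuropil trace; returning alpha = 0")
    return(list(F_corrected = F_soma, alpha = 0, degenerate = TRUE))
  }
  f <- function(a) {
    r <- suppressWarnings(stats::cor(F_soma - a * np_c, F_neuropil))
    if (is.na(r)) 0 else abs(r)
  }
  opt <- stats::optimize(f, c(0, 1), tol = 1e-6)
  # the endpoints can beat the interior optimum when the zero crossing of the
  # correlation lies outside [0, 1]
  cand <- c(0, opt$minimum, 1)
  alpha <- cand[which.min(vapply(cand, f, numeric(1)))]
  list(F_corrected = F_soma - alpha * np_c, alpha = alpha, degenerate = FALSE)
}

#' Compute dF/F with a density-mode baseline
#'
#' `dF/F = (F - F0) / F0`, with `F0` the mode of the corrected-fluorescence
#' density (Gaussian kernel, Silverman bandwidth, argmax over the density
#' grid). Constant traces use their value as `F0` directly.
#'
#' @param F_corrected numeric vector.
#' @return list with `dff` and `F0`.
#' @export
compute_dff <- function(F_corrected) {
  if (anyNA(F_corrected)) stop("F_corrected contains NA")
  if (stats::sd(F_corrected) < .Machine$double.eps^0.5) {
    F0 <- F_corrected[1]
  } else {
    d <- stats::density(F_corrected, bw = "nrd0", n = 2048)
    F0 <- d$x[which.max(d$y)]
  }
  if (F0 <= 0) stop("nonpositive baseline F0; pathological trace")
  list(dff = (F_corrected - F0) / F0, F0 = F0)
}

#' Estimate the AR(1) calcium decay coefficient from a trace
#'
#' Ratio of autocovariances at lags 2 and 1, which is robust to additive
#' white noise for an AR(1) transient process; clamped to (0.5, 0.99). Note
#' that strong slow firing-rate modulation (e.g. a tuning bump swept at
#' rotation speed) inflates the trace autocorrelation and biases this
#' estimator upward, which is why [deconvolve_ar1()] defaults to a fixed
#' physiological coefficient rather than `"auto"`.
#'
#' @param x numeric trace.
#' @return gamma estimate in (0, 1).
#' @export
estimate_ar1_gamma <- function(x) {
  if (stats::sd(x) < .Machine$double.eps^0.5) return(0.9)
  ac <- stats::acf(x, lag.max = 2, plot = FALSE, demean = TRUE)$acf
  g <- if (abs(ac[2]) < 1e-8) 0.9 else ac[3] / ac[2]
  min(max(g, 0.5), 0.99)
}

#' Nonnegative AR(1) deconvolution of a dF/F trace
#'
#' Inverts the AR(1) convolution (`s_t = y_t - gamma * y_{t-1}`) and keeps
#' the nonnegative part above a noise threshold. The threshold is
#' `thresh_k` times a robust noise estimate (MAD of the innovation series);
#' with a noiseless input the threshold is 0 and the inversion is exact.
#'
#' @param dff numeric vector.
#' @param gamma AR(1) coefficient in (0, 1); the default 0.9 corresponds to
#'   a ~1 s indicator decay at 10 Hz. `"auto"` estimates it with
#'   [estimate_ar1_gamma()] (appropriate only when firing is not dominated by
#'   slow stimulus-locked modulation).
#' @param thresh_k noise-threshold multiplier (default 2).
#' @return nonnegative spike amplitude series, same length as `dff`, with the
#'   used `gamma` as attribute.
#' @export
deconvolve_ar1 <- function(dff, gamma = 0.9, thresh_k = 2) {
  if (anyNA(dff) || any(!is.finite(dff))) stop("dff must be finite")
  if (identical(gamma, "auto")) gamma <- estimate_ar1_gamma(dff)
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1)
    stop("gamma must lie strictly between 0 and 1")
  n <- length(dff)
  innov <- c(dff[1], dff[-1] - gamma * dff[-n])
  sigma <- stats::mad(innov, center = 0)
  s <- innov - thresh_k * sigma
  s[s < 0] <- 0
  attr(s, "gamma") <- gamma
  s
}

#' Reconvolve a spike series through the AR(1) kernel
#' @param spikes nonnegative series.
#' @param gamma AR(1) coefficient.
#' @return calcium-like trace.
#' @export
reconvolve_ar1 <- function(spikes, gamma) {
  as.numeric(stats::filter(spikes, gamma, method = "recursive"))
}

#' Remove duplicate ROIs by trace correlation
#'
#' ROIs whose traces have Pearson correlation above `r_threshold` are grouped
#' into connected components; one representative per component (the trace with
#' highest variance) is kept.
#'
#' @param traces cells x frames matrix.
#' @param r_threshold correlation threshold (default 0.5; strictly greater
#'   correlations count as duplicates).
#' @return integer vector of retained row indices, in increasing order.
#' @export
deduplicate_rois <- function(traces, r_threshold = 0.5) {
  n <- nrow(traces)
  if (n < 1L) stop("need at least one ROI")
  if (n == 1L) return(1L)
  cm <- suppressWarnings(stats::cor(t(traces)))
  cm[is.na(cm)] <- 0
  adj <- cm > r_threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  vars <- apply(traces, 1, stats::var)
  keep <- vapply(seq_len(cur), function(g) {
    members <- which(comp == g)
    members[which.max(vars[members])]
  }, integer(1))
  sort(keep)
}

#' Full trace-processing stage
#'
#' Runs neuropil correction, dF/F conversion and AR(1) deconvolution for every
#' cell of a trace set, then flags duplicate ROIs.
#'
#' @param traces a `roi_trace_set` (see [simulate_traces()]).
#' @param gamma AR(1) coefficient (default 0.9) or `"auto"` (per cell).
#' @param r_threshold duplicate-ROI correlation threshold.
#' @return list of class `processed_traces`: matrices `F_corrected`, `dff`,
#'   `spikes`; vectors `alpha`, `F0`, `gamma`; `kept` (indices surviving
#'   deduplication); `frame_rate`.
#' @export
process_traces <- function(traces, gamma = 0.9, r_threshold = 0.5) {
  stopifnot(inherits(traces, "roi_trace_set"))
  n <- nrow(traces$F_soma)
  Fc <- dff <- sp <- matrix(0, n, ncol(traces$F_soma))
  alpha <- F0 <- gam <- numeric(n)
  for (i in seq_len(n)) {
    nc <- neuropil_correct(traces$F_soma[i, ], traces$F_neuropil[i, ])
    dd <- compute_dff(nc$F_corrected)
    s <- deconvolve_ar1(dd$dff, gamma = gamma)
    Fc[i, ] <- nc$F_corrected
    dff[i, ] <- dd$dff
    sp[i, ] <- s
    alpha[i] <- nc$alpha
    F0[i] <- dd$F0
    gam[i] <- attr(s, "gamma")
  }
  kept <- deduplicate_rois(dff, r_threshold)
  structure(list(F_corrected = Fc, dff = dff, spikes = sp, alpha = alpha,
                 F0 = F0, gamma = gam, kept = kept,
                 frame_rate = traces$frame_rate),
            class = "processed_traces")
}

#' @export
print.processed_traces <- function(x, ...) {
  cat(sprintf("processed_traces: %d cells x %d frames (%d kept after deduplication)\n",
              nrow(x$dff), ncol(x$dff), length(x$kept)))
  cat(sprintf("  alpha median %.2f; F0 median %.2f\n",
              stats::median(x$alpha), stats::median(x$F0)))
  invisible(x)
}
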