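#' Simulate soma and neuropil fluorescence from a ground-truth population
#'
#' Forward model of the imaging data: per-frame spikes are Poisson with the
#' cell's heading- and light-dependent rate; calcium follows an AR(1) impulse
#' response of the spikes (`c_t = gamma * c_{t-1} + s_t`); somatic fluorescence
#' is baseline + calcium + additive Gaussian noise, contaminated by the shared
#' neuropil signal scaled by the cell's `neuropil_alpha`. The neuropil trace
#' is a baseline plus a slow shared background process (AR(1)-smoothed noise,
#' ~seconds timescale) with per-cell measurement noise: non-constant and
#' common across cells, but independent of any one cell's spiking, as for
#' out-of-focus background fluorescence.
#'
#' @param pop a [generate_population()] data frame.
#' @param track a [generate_session()] tracking series.
#' @param f_baseline somatic fluorescence baseline (a.u.).
#' @param calcium_amp fluorescence per unit calcium (a.u.).
#' @param neuropil_baseline,neuropil_amp,neuropil_noise_sd neuropil signal
#'   parameters (a.u.).
#' @param seed integer seed.
#' @return list with `traces` (a `roi_trace_set`: `F_soma`, `F_neuropil`
#'   cells x frames matrices, `frame_rate`, `provenance`) and `spikes`
#'   (ground-truth spike counts, cells x frames).
#' @export
simulate_traces <- function(pop, track,
                            f_baseline = 1,
                            calcium_amp = 0.2,
                            neuropil_baseline = 1,
                            neuropil_amp = 0.1,
                            neuropil_noise_sd = 0.02,
                            seed = 1L) {
  if (!inherits(track, "tracking_series")) stop("track must be a tracking_series")
  n_cells <- nrow(pop)
  n_frames <- nrow(track)
  fr <- attr(track, "frame_rate")
  dt <- 1 / fr
  set.seed(seed)
  spikes <- matrix(0, n_cells, n_frames)
  calcium <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    rate <- cell_rate(pop[i, ], track$heading, track$light_on)
    s <- stats::rpois(n_frames, rate * dt)
    spikes[i, ] <- s
    calcium[i, ] <- stats::filter(s, pop$calcium_gamma[i], method = "recursive")
  }
  # slow shared background, ~2 s correlation time at the default frame rate
  g_bg <- exp(-1 / (2 * fr))
  bg <- as.numeric(stats::filter(stats::rnorm(n_frames), g_bg,
                                 method = "recursive"))
  bg <- bg / max(stats::sd(bg), .Machine$double.eps)
  F_neuropil <- matrix(rep(neuropil_baseline + neuropil_amp * bg,
                           each = n_cells), n_cells, n_frames) +
    matrix(stats::rnorm(n_cells * n_frames, 0, neuropil_noise_sd),
           n_cells, n_frames)
  F_soma <- f_baseline + calcium_amp * calcium +
    pop$neuropil_alpha * F_neuropil +
    matrix(stats::rnorm(n_cells * n_frames, 0, rep(pop$noise_sd, n_frames)),
           n_cells, n_frames)
  traces <- structure(
    list(F_soma = F_soma, F_neuropil = F_neuropil, frame_rate = fr,
         provenance = "synthetic"),
    class = "roi_trace_set")
  list(traces = traces, spikes = spikes)
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("roi_trace_set (%s): %d cells x %d frames at %g Hz\n",
              x$provenance, nrow(x$F_soma), ncol(x$F_soma), x$frame_rate))
  invisible(x)
}
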