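#' Validation benchmarks
#'
#' Self-contained benchmark routines that measure the pipeline's calibration
#' and recovery properties on synthetic data: decoder chance level, the
#' false-positive rate of the trial-based selectivity test, silhouette
#' cluster-number selection, parameter recovery, the class-wise decoding
#' light-dependence pattern, and the coherent-remapping statistic. They are
#' used by the package's acceptance tests and by `scripts/acceptance.R`.
#'
#' @name benchmarks
NULL

#' Chance level of the decoder-accuracy metric
#'
#' The accuracy metric counts decoded frames whose circular error is below
#' the 18-degree window, so uniformly random decoding has expectation
#' 2 x 18 / 360 = 0.10. Returns the analytic value together with a large-n
#' simulation scored through [decoder_metrics()].
#'
#' @param n_frames simulated frames (default 1e6).
#' @param window accuracy window in degrees (default 18).
#' @param seed integer seed.
#' @return list with `analytic`, `simulated`, `n_frames`.
#' @export
benchmark_chance_accuracy <- function(n_frames = 1e6, window = 18, seed = 1L) {
  set.seed(seed)
  decoded <- stats::runif(n_frames, 0, 360)
  actual <- stats::runif(n_frames, 0, 360)
  m <- decoder_metrics(decoded, actual, window = window)
  list(analytic = 2 * window / 360, simulated = m$accuracy,
       n_frames = n_frames)
}

#' False-positive rate of the trial-based selectivity test on null cells
#'
#' Simulates untuned cells as homogeneous Poisson spike trains over
#' full-rotation trials and runs the complete trial-based selectivity
#' procedure (split-half KS + Cohen's d + Gaussian-fit r-squared against the
#' shuffle 90th percentile) at the standard thresholds.
#'
#' @param n_cells number of null cells (default 2000).
#' @param n_trials full-rotation trials per cell (default 6).
#' @param rate homogeneous firing rate in spikes/s (default 0.5, the
#'   generator's untuned baseline).
#' @param n_shuffles split/shuffle repetitions (default 200).
#' @param seed integer seed.
#' @return list with `rate_selective` (fraction declared selective), `n`,
#'   `ci_low`, `ci_high` (95% binomial CI), and the per-cell verdicts.
#' @export
benchmark_null_selectivity <- function(n_cells = 2000, n_trials = 6,
                                       rate = 0.5, n_shuffles = 200,
                                       seed = 1L) {
  sc <- session_config(n_repeats = n_trials,
                       rotation_duration = 12.4,  # one rotation per repeat
                       rotation_speed = 5, seed = seed)
  track <- generate_session(sc)
  fr <- attr(track, "frame_rate")
  set.seed(seed + 1L)
  hits <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    s <- stats::rpois(nrow(track), rate / fr)
    cv <- tuning_curve(s, track)
    hits[i] <- trialwise_selectivity(cv$per_trial,
                                     n_shuffles = n_shuffles)$selective
  }
  p <- mean(hits)
  ci <- stats::binom.test(sum(hits), n_cells)$conf.int
  list(rate_selective = p, n = n_cells, ci_low = ci[1], ci_high = ci[2],
       hits = hits)
}

#' Silhouette cluster-number selection on three-class populations
#'
#' For each seed, generates a high-SNR population of heading, landmark and
#' alignment cells at the tuned-class proportions of the emulated study
#' (0.22 : 0.33 : 0.28, renormalised), simulates a light-on/light-off
#' session, runs the fit-and-cluster pipeline, and records the
#' silhouette-selected number of clusters.
#'
#' @param n_cells tuned cells per repetition (default 150).
#' @param n_seeds repetitions (default 20).
#' @param seed base seed.
#' @return list with `k` (vector over seeds), `k_majority`,
#'   `fraction_k3`, `n_cells`.
#' @export
benchmark_cluster_number <- function(n_cells = 150, n_seeds = 20, seed = 1L) {
  mix <- c(heading = 0.22, landmark = 0.33, alignment = 0.28)
  mix <- mix / sum(mix)
  ks <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    base <- seed * 1000L + s
    track <- generate_session(session_config(n_repeats = 4,
                                             rotation_duration = 96,
                                             seed = base))
    pop <- generate_population(n_cells, class_mix = mix, peak_rate = 20,
                               baseline_rate = 0.5, noise_sd = 0.01,
                               seed = base + 1L)
    sim <- simulate_traces(pop, track, seed = base + 2L)
    cl <- classify_population(sim$spikes, track, seed = base + 3L)
    ks[s] <- cl$clustering$k_selected
  }
  tab <- table(ks)
  list(k = ks, k_majority = as.integer(names(tab)[which.max(tab)]),
       fraction_k3 = mean(ks == 3L), n_cells = n_cells)
}

#' Parameter-recovery benchmarks
#'
#' Three recovery checks against ground truth: preferred directions of
#' high-SNR tuned cells (peak rate 30 spikes/s — strong enough that the
#' check probes the estimator rather than Poisson sampling noise — via
#' tuning curves from the generator's spikes over a full-protocol session),
#' the neuropil mixing fraction alpha on synthetic mixtures with independent
#' somatic signal, and sum-of-Gaussians coefficients refit from noiseless
#' self-generated curves.
#'
#' @param n_cells tuned cells for the preferred-direction check
#'   (default 150).
#' @param n_mixtures alpha-recovery mixtures (default 30).
#' @param seed integer seed.
#' @return list with `pref_within_6deg` (fraction), `pref_err` (signed
#'   errors), `alpha_max_err`, `gauss_max_rel_err`.
#' @export
benchmark_recovery <- function(n_cells = 150, n_mixtures = 30, seed = 1L) {
  # preferred-direction recovery at high SNR, full protocol length
  track <- generate_session(session_config(n_repeats = 6,
                                           rotation_duration = 96,
                                           seed = seed))
  pop <- generate_population(n_cells, class_mix = c(heading = 1),
                             peak_rate = 30, baseline_rate = 0.5,
                             noise_sd = 0.01, seed = seed + 1L)
  sim <- simulate_traces(pop, track, seed = seed + 2L)
  curves <- compute_tuning_curves(sim$spikes, track)
  pref <- vapply(curves, preferred_direction, numeric(1))
  err <- circ_diff(pref, pop$preferred_deg)
  # alpha recovery on independent-signal mixtures
  set.seed(seed + 3L)
  n <- 3000
  a_err <- vapply(seq_len(n_mixtures), function(i) {
    np <- as.numeric(stats::filter(stats::rnorm(n), 0.8,
                                   method = "recursive")) + 5
    s <- abs(stats::rnorm(n))
    a_true <- stats::runif(1, 0.05, 0.95)
    abs(neuropil_correct(s + a_true * np, np)$alpha - a_true)
  }, numeric(1))
  # sum-of-Gaussians coefficient recovery from noiseless curves
  set.seed(seed + 4L)
  g_err <- vapply(1:10, function(i) {
    co <- c(a0 = stats::runif(1, 0, 0.5), a1 = stats::runif(1, 0.8, 2),
            b1 = stats::runif(1, 0, 360), c1 = stats::runif(1, 20, 45),
            a2 = stats::runif(1, 0.3, 0.8), b2 = NA, c2 = stats::runif(1, 20, 45))
    co["b2"] <- wrap360(co[["b1"]] + 180)
    y <- eval_sum_of_gaussians(co, bin_centers_deg(60))
    f <- fit_sum_of_gaussians(y, n_terms = 2)
    idx <- c("a0", "a1", "c1", "a2", "c2")
    max(abs((f$coef[idx] - co[idx]) / co[idx]))
  }, numeric(1))
  list(pref_within_6deg = mean(abs(err) <= 6), pref_err = err,
       alpha_max_err = max(a_err), gauss_max_rel_err = max(g_err))
}

#' Class-wise decoding pattern across light conditions
#'
#' Simulates a balanced three-class population, decodes bootstrap
#' pseudopopulations per class, and returns the light-on/light-off accuracy
#' summaries whose pattern characterises the classes: heading stable,
#' landmark collapsing to chance in darkness, alignment retaining
#' above-chance dark accuracy.
#'
#' @param n_cells total cells (default 120, equal class thirds).
#' @param n_boot bootstrap iterations per class (default 50).
#' @param seed integer seed.
#' @return named list per class (`heading`, `landmark`, `alignment`,
#'   `all_tuned`) of [decode_population()] results.
#' @export
benchmark_class_decoding <- function(n_cells = 120, n_boot = 50, seed = 1L) {
  track <- generate_session(session_config(n_repeats = 4,
                                           rotation_duration = 96,
                                           seed = seed))
  pop <- generate_population(n_cells,
                             class_mix = c(heading = 1/3, landmark = 1/3,
                                           alignment = 1/3),
                             peak_rate = 20, baseline_rate = 0.5,
                             noise_sd = 0.01, seed = seed + 1L)
  sim <- simulate_traces(pop, track, seed = seed + 2L)
  aligned <- suppressWarnings(resample_trials(sim$spikes, track))
  out <- lapply(stats::setNames(nm = c("all_tuned", "heading", "landmark",
                                       "alignment")),
                function(f) decode_population(aligned, pop$class,
                                              class_filter = f,
                                              n_boot = n_boot,
                                              seed = seed + 3L))
  out
}

#' Coherent-remapping calibration
#'
#' Checks the two ends of the delta-phase-offset statistic: a fully coherent
#' remap must give exactly zero offsets for every cell, and re-pairing cells
#' at random (the shuffled-pair control) must give a near-uniform
#' distribution.
#'
#' @param n_cells cells per population (default 100).
#' @param n_seeds repetitions for the shuffled-pair control (default 20).
#' @param seed base seed.
#' @return list with `coherent_max_abs` (degrees, over one coherent remap)
#'   and `uniform_ks_pass` (fraction of seeds with KS p > 0.05 against the
#'   uniform).
#' @export
benchmark_remapping <- function(n_cells = 100, n_seeds = 20, seed = 1L) {
  set.seed(seed)
  pop <- generate_population(n_cells, class_mix = c(heading = 1),
                             seed = seed)
  rot <- apply_remap(pop, 137)
  coh <- delta_phase_offset(pop$preferred_deg, rot$preferred_deg)
  pass <- vapply(seq_len(n_seeds), function(s) {
    set.seed(seed * 100L + s)
    a <- stats::runif(n_cells, 0, 360)
    b <- (a - stats::runif(1, 0, 360)) %% 360     # coherent population
    d <- shuffled_pair_control(a, b, seed = seed * 100L + s)$delta_phase_offset
    suppressWarnings(stats::ks.test(d, "punif", -180, 180)$p.value) > 0.05
  }, logical(1))
  list(coherent_max_abs = max(abs(coh$delta_phase_offset)),
       uniform_ks_pass = mean(pass))
}
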