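# Shared fixtures, built in code. Small sessions keep the suite fast while
# preserving the protocol structure (full rotations, rests, light switches).

# short controlled session: `reps` repeats of `rots` rotations each
# (3% duration slack so speed jitter cannot drop the final rotation)
fix_session <- function(reps = 4, rots = 2, rpm = 5, seed = 1, ...) {
  generate_session(session_config(
    n_repeats = reps, rotation_speed = rpm,
    rotation_duration = rots * 60 / rpm * 1.03, seed = seed, ...))
}

# high-SNR population of a given composition
fix_population <- function(n, mix, seed = 1, ...) {
  generate_population(n, class_mix = mix, peak_rate = 20,
                      baseline_rate = 0.5, noise_sd = 0.01, seed = seed, ...)
}

# deterministic spike matrix for decoder tests: one "one-hot" cell per heading
# bin, firing iff the heading falls in its bin
fix_onehot_spikes <- function(track, n_bins = 60) {
  bins <- findInterval(track$heading %% 360, seq(0, 360, by = 360 / n_bins),
                       rightmost.closed = TRUE)
  bins[bins > n_bins] <- n_bins
  t(vapply(seq_len(n_bins), function(b) as.numeric(bins == b),
           numeric(nrow(track))))
}

bin_centers <- function(n = 60) (seq_len(n) - 0.5) * 360 / n
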