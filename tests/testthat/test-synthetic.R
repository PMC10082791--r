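test_that("controlled sessions have full-rotation trials, rests, and gated lights", {
  tr <- fix_session(reps = 4, rots = 2, seed = 1)
  expect_s3_class(tr, "tracking_series")
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(tr$heading >= 0 & tr$heading < 360))
  tl <- trial_light(tr)
  expect_length(tl, 8)              # 2 rotations x 4 repeats
  expect_true(tl[["1"]])            # first repeat light-on
  # every trial visits all 60 heading bins
  for (id in as.integer(names(tl))) {
    h <- tr$heading[!is.na(tr$trial_id) & tr$trial_id == id]
    bins <- findInterval(h, seq(0, 360, by = 6), rightmost.closed = TRUE)
    expect_equal(length(unique(pmin(bins, 60))), 60)
  }
  # light switches only during rest frames
  switches <- which(diff(tr$light_on) != 0)
  expect_true(all(tr$is_rest[switches] | tr$is_rest[switches + 1]))
  # rest gaps have the configured length
  expect_equal(sum(tr$is_rest), 3 * 5 * 10)
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(fix_session(seed = 7), fix_session(seed = 7))
  p1 <- generate_population(50, seed = 3)
  p2 <- generate_population(50, seed = 3)
  expect_identical(p1, p2)
  tr <- fix_session(reps = 2, rots = 1)
  s1 <- simulate_traces(p1[1:5, ], tr, seed = 11)
  s2 <- simulate_traces(p1[1:5, ], tr, seed = 11)
  expect_identical(s1, s2)
})

test_that("population class counts follow the requested mix", {
  mix <- c(heading = 0.121 * 0.39, landmark = 0.121 * 0.33,
           alignment = 0.121 * 0.28, untuned = 0.879)
  pop <- generate_population(1000, class_mix = mix, seed = 5)
  cnt <- table(pop$class)
  expect_equal(unname(cnt[["landmark"]]), round(1000 * mix[["landmark"]]),
               tolerance = 1)
  expect_equal(sum(pop$class != "untuned"), 121, tolerance = 1)
  expect_equal(nrow(generate_population(0)), 0)
  expect_error(generate_population(10, class_mix = c(heading = -0.5, untuned = 1.5)),
               "nonnegative")
  # preferred directions uniform: pooled RVL near 0
  big <- generate_population(10000, class_mix = c(heading = 1), seed = 8)
  expect_lt(rayleigh_vector_length(big$preferred_deg), 0.03)
})

test_that("simulated traces follow the forward model", {
  tr <- fix_session(reps = 2, rots = 1)
  # silent cell with zero noise: flat trace at baseline + alpha * neuropil
  pop <- generate_population(2, class_mix = c(untuned = 1), baseline_rate = 0,
                             noise_sd = 0, seed = 2)
  sim <- simulate_traces(pop, tr, neuropil_amp = 0, neuropil_noise_sd = 0,
                         seed = 3)
  expect_equal(sum(sim$spikes), 0)
  expect_equal(stats::sd(sim$traces$F_soma[1, ]), 0, tolerance = 1e-12)
  # single forced spike through the AR(1) kernel
  gamma <- 0.9
  imp <- reconvolve_ar1(c(1, rep(0, 49)), gamma)
  expect_equal(imp, gamma^(0:49))
  # landmark cells fall to baseline in darkness
  tr2 <- fix_session(reps = 4, rots = 2)
  popl <- generate_population(20, class_mix = c(landmark = 1),
                              baseline_rate = 0.5, peak_rate = 10, seed = 4)
  siml <- simulate_traces(popl, tr2, seed = 5)
  off <- !tr2$light_on
  rate_off <- mean(siml$spikes[, off]) * attr(tr2, "frame_rate")
  expect_lt(abs(rate_off - 0.5), 0.05)
  # and well below the light-on rate of the same cells
  expect_gt(mean(siml$spikes[, !off]) * 10, 2 * rate_off)
})

test_that("remapping rotates tuned cells and spares untuned ones", {
  pop <- generate_population(500, class_mix = c(heading = 0.5, untuned = 0.5),
                             seed = 6)
  expect_identical(apply_remap(pop, 0), pop)
  rot <- apply_remap(pop, 90)
  tuned <- pop$class != "untuned"
  expect_equal(circ_diff(rot$preferred_deg[tuned], pop$preferred_deg[tuned]),
               rep(90, sum(tuned)))
  expect_identical(rot$preferred_deg[!tuned], pop$preferred_deg[!tuned])
  # incoherent fraction: about 20% of tuned cells deviate from the common shift
  rin <- apply_remap(pop, 90, incoherent_fraction = 0.2, seed = 9)
  dev <- circ_dist(circ_diff(rin$preferred_deg[tuned], pop$preferred_deg[tuned]), 90)
  expect_equal(mean(dev > 1e-9), 0.2, tolerance = 0.05)
})
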