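test_that("trial resampling yields 200 bins and handles the wrap cleanly", {
  tr <- fix_session(reps = 2, rots = 2, seed = 1)
  set.seed(2)
  act <- matrix(rpois(3 * nrow(tr), 0.3), 3)
  al <- resample_trials(act, tr)
  expect_s3_class(al, "aligned_trials")
  expect_equal(dim(al$activity)[3], 200)
  expect_equal(nrow(al$heading), dim(al$activity)[2])
  # constant activity stays constant
  al2 <- resample_trials(matrix(2, 1, nrow(tr)), tr)
  expect_equal(range(al2$activity), c(2, 2))
  # wrap handling: resampled heading is monotone on the unwrapped circle,
  # with no interpolation artifact jumping toward 180
  for (k in seq_len(nrow(al$heading))) {
    dh <- circ_diff(al$heading[k, -1], al$heading[k, -200])
    expect_true(all(dh > 0))
    expect_lt(max(dh), 6)
  }
  # heading spans the full circle each trial
  expect_true(all(apply(al$heading, 1, function(h)
    length(unique(floor(h / 6))) == 60)))
})

test_that("partial rotations are excluded with a warning", {
  tr <- fix_session(reps = 2, rots = 2, seed = 3)
  tr2 <- tr
  keep <- !is.na(tr2$trial_id) & tr2$trial_id == 1
  # cut away the second half of trial 1's frames
  drop <- which(keep)[seq(sum(keep) %/% 2, sum(keep))]
  tr2 <- tr2[-drop, ]
  attr(tr2, "frame_rate") <- attr(tr, "frame_rate")
  class(tr2) <- class(tr)
  act <- matrix(1, 1, nrow(tr2))
  expect_warning(al <- resample_trials(act, tr2), "spans only")
  expect_false(1L %in% al$trial_ids)
})

test_that("pseudopopulation draws respect class sizes and proportions", {
  labels <- c(rep("heading", 400), rep("landmark", 350), rep("alignment", 332))
  draws <- build_pseudopopulation(labels, "landmark", n_boot = 5, seed = 1)
  expect_length(draws, 5)
  expect_length(draws[[1]], 332)     # smallest class sets the sample size
  expect_true(all(labels[draws[[2]]] == "landmark"))
  # all-tuned mode preserves rough class proportions
  draws2 <- build_pseudopopulation(labels, "all_tuned", n_boot = 200, seed = 2)
  tallied <- table(labels[unlist(draws2)]) / (200 * 332)
  expect_equal(unname(tallied[["heading"]]), 400 / 1082, tolerance = 0.02)
  expect_equal(unname(tallied[["alignment"]]), 332 / 1082, tolerance = 0.02)
  # determinism and error cases
  expect_identical(build_pseudopopulation(labels, "heading", n_boot = 2, seed = 7),
                   build_pseudopopulation(labels, "heading", n_boot = 2, seed = 7))
  expect_error(build_pseudopopulation(rep("untuned", 10), "heading"), "no tuned")
})

test_that("noiseless one-hot populations decode with zero error", {
  tr <- fix_session(reps = 2, rots = 2, seed = 4)
  spikes <- fix_onehot_spikes(tr)
  al <- resample_trials(spikes, tr)
  res <- decode_bayes(al)
  expect_s3_class(res, "decode_result")
  expect_lt(max(res$error), 6 + 1e-9)   # within one bin everywhere
  expect_equal(res$accuracy, 1)
  # a global bin-aligned rotation of all headings leaves the error invariant
  al_rot <- al
  al_rot$heading <- (al$heading + 126) %% 360
  res_rot <- decode_bayes(al_rot)
  expect_equal(res_rot$accuracy, res$accuracy)
  expect_equal(sort(res_rot$error), sort(res$error), tolerance = 1e-9)
})

test_that("decoder metrics implement circular error and the 18-degree window", {
  m <- decoder_metrics(c(0, 90, 359, 180), c(359, 270, 0, 0))
  expect_equal(m$error, c(1, 180, 1, 180))
  expect_equal(m$accuracy_per_trial, 0.5)
  # perfect and antipodal decoders
  h <- runif(500, 0, 360)
  expect_equal(decoder_metrics(h, h)$accuracy, 1)
  expect_equal(decoder_metrics((h + 180) %% 360, h)$accuracy, 0)
  expect_equal(decoder_metrics(rep(90, 4), rep(0, 4))$accuracy, 0)
  # uniform random decoding hits the 0.10 chance level
  set.seed(5)
  u <- decoder_metrics(runif(2e5, 0, 360), runif(2e5, 0, 360))
  expect_equal(u$accuracy, 0.10, tolerance = 0.01)
  expect_error(decoder_metrics(numeric(0), numeric(0)), "empty")
})

test_that("bootstrap summaries use percentile CIs and flag significance", {
  acc <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  b <- bootstrap_accuracy(acc)
  expect_equal(b$mean, 0.7)
  expect_equal(b$ci_low, unname(quantile(acc, 0.025)))
  expect_equal(b$ci_high, unname(quantile(acc, 0.975)))
  expect_true(b$significant)
  expect_equal(b$median_iteration, 3)
  # identical iterations: zero-width CI
  b2 <- bootstrap_accuracy(rep(0.4, 10))
  expect_equal(b2$ci_low, b2$ci_high)
  expect_error(bootstrap_accuracy(0.5), "at least 2")
})

test_that("class-wise decoding reproduces the light-dependence pattern", {
  tr <- generate_session(session_config(n_repeats = 4, rotation_duration = 96,
                                        seed = 51))
  pop <- generate_population(90, class_mix = c(heading = 1/3, landmark = 1/3,
                                               alignment = 1/3),
                             peak_rate = 20, baseline_rate = 0.5,
                             noise_sd = 0.01, seed = 52)
  sim <- simulate_traces(pop, tr, seed = 53)
  al <- suppressWarnings(resample_trials(sim$spikes, tr))
  dec <- lapply(c(heading = "heading", landmark = "landmark",
                  alignment = "alignment"), function(f)
    decode_population(al, pop$class, class_filter = f, n_boot = 30, seed = 54))
  # landmark: high in light, chance in darkness
  expect_gt(dec$landmark$summary_on$mean, 0.5)
  expect_lt(dec$landmark$summary_off$mean, 0.15)
  # heading: stable across conditions, much smaller drop than landmark
  drop_heading <- abs(dec$heading$summary_on$mean - dec$heading$summary_off$mean)
  drop_landmark <- dec$landmark$summary_on$mean - dec$landmark$summary_off$mean
  expect_lt(drop_heading, drop_landmark)
  # alignment: above chance in darkness
  expect_gt(dec$alignment$summary_off$ci_low, 0.10)
  # bimodal landmark cells produce 180-degree errors in light
  resL <- decode_bayes(subset_aligned(al, cells = which(pop$class == "landmark"),
                                      trials = which(al$light_on)))
  err <- resL$error
  expect_gt(mean(err > 150), mean(err > 60 & err < 120))
})
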