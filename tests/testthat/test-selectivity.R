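test_that("RVL selectivity separates delta-tuned from uniform cells", {
  # voluntary session: the time-shift shuffle needs an irregular trajectory
  tr <- generate_session(session_config(mode = "voluntary", duration = 400,
                                        seed = 1))
  set.seed(2)
  # noiseless delta-tuned cell: fires only in one bin
  s_delta <- as.numeric(tr$heading >= 120 & tr$heading < 126)
  r <- rvl_selectivity(s_delta, tr$heading, n_shuffles = 200)
  expect_gt(r$rvl, 0.95)
  expect_true(r$selective)
  expect_lt(circ_dist(r$preferred_deg, 123), 6)
  # uniform Poisson rate: low RVL, not selective
  r2 <- rvl_selectivity(rpois(nrow(tr), 0.5), tr$heading, n_shuffles = 200)
  expect_lt(r2$rvl, 0.2)
  expect_false(r2$selective)
  # zero spikes and constant series: undefined flag
  r3 <- rvl_selectivity(rep(0, nrow(tr)), tr$heading, n_shuffles = 50)
  expect_true(r3$undefined)
  expect_false(r3$selective)
  expect_false(rvl_selectivity(rep(2, nrow(tr)), tr$heading,
                               n_shuffles = 50)$selective)
})

test_that("RVL shuffle test false-positive rate is near its nominal 1%", {
  tr <- generate_session(session_config(mode = "voluntary", duration = 300,
                                        seed = 3))
  set.seed(4)
  n_null <- 300
  hits <- vapply(seq_len(n_null), function(i) {
    s <- rpois(nrow(tr), 0.1)
    rvl_selectivity(s, tr$heading, n_shuffles = 200)$selective
  }, logical(1))
  # nominal 0.01; allow binomial spread at n=300
  expect_lte(mean(hits), 0.035)
})

test_that("trial-based test passes strongly tuned cells and honours strict thresholds", {
  tr <- fix_session(reps = 6, rots = 2, seed = 5)
  pop <- fix_population(3, c(heading = 1), seed = 6)
  sim <- simulate_traces(pop, tr, seed = 7)
  set.seed(8)
  for (i in 1:3) {
    cv <- tuning_curve(sim$spikes[i, ], tr)
    res <- trialwise_selectivity(cv$per_trial, n_shuffles = 200)
    expect_true(res$selective)
    expect_lt(res$ks_p, 0.1)
    expect_gt(res$cohens_d, 0.8)
    expect_gt(res$r2_real, res$r2_shuffle_q90)
    expect_lt(circ_dist(res$preferred_deg, pop$preferred_deg[i]), 12)
  }
  expect_error(trialwise_selectivity(matrix(1, 3, 60)), "at least 4 trials")
})

test_that("selectivity verdict uses strict inequalities at the thresholds", {
  # exercise the decision rule directly via threshold arguments: with the
  # observed statistics sitting exactly at the thresholds the verdict is no
  tr <- fix_session(reps = 6, rots = 2, seed = 5)
  pop <- fix_population(1, c(heading = 1), seed = 6)
  sim <- simulate_traces(pop, tr, seed = 7)
  cv <- tuning_curve(sim$spikes[1, ], tr)
  set.seed(12)
  base <- trialwise_selectivity(cv$per_trial, n_shuffles = 100)
  expect_true(base$selective)
  # raise the d threshold to the observed value: strict '>' must now fail
  set.seed(12)
  at_d <- trialwise_selectivity(cv$per_trial, n_shuffles = 100,
                                d_threshold = base$cohens_d)
  expect_false(at_d$selective)
  # lower the KS alpha to the observed p: strict '<' must fail
  set.seed(12)
  at_ks <- trialwise_selectivity(cv$per_trial, n_shuffles = 100,
                                 ks_alpha = base$ks_p)
  expect_false(at_ks$selective)
})
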