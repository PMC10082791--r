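test_that("tuning curves localise responses and respect light conditions", {
  tr <- fix_session(reps = 4, rots = 2, seed = 1)
  # spikes only when heading in [87, 93): peak in the bin containing 90
  s <- as.numeric(tr$heading >= 87 & tr$heading < 93 & !tr$is_rest)
  cv <- tuning_curve(s, tr)
  expect_length(cv$mean_curve, 60)
  # peak must be within one bin of 90 after the 3-bin smoothing
  expect_lt(circ_dist(preferred_direction(cv), 90), 6 + 1e-9)
  # uniform constant rate: flat curve up to sampling noise (here exact)
  su <- rep(1, nrow(tr))
  cvu <- tuning_curve(su, tr)
  expect_lt(diff(range(cvu$mean_curve)), 1e-9)
  # light filters select matching trials only
  tl <- trial_light(tr)
  cv_on <- tuning_curve(su, tr, condition = "light_on")
  cv_off <- tuning_curve(su, tr, condition = "light_off")
  expect_equal(nrow(cv_on$per_trial), sum(tl))
  expect_equal(nrow(cv_off$per_trial), sum(!tl))
  expect_true(all(cv_on$trial_ids %in% as.integer(names(tl)[tl])))
})

test_that("long sessions recover the generating rate map", {
  tr <- fix_session(reps = 6, rots = 4, seed = 2)
  pop <- fix_population(1, c(heading = 1), seed = 3)
  sim <- simulate_traces(pop, tr, seed = 4)
  cv <- tuning_curve(sim$spikes[1, ], tr)
  truth <- cell_rate(pop[1, ], cv$bin_centers, TRUE)
  # compare smoothed analytic map to the estimate, relative to peak rate
  truth_sm <- as.numeric(stats::filter(c(tail(truth, 1), truth, truth[1]),
                                       rep(1 / 3, 3)))[2:61]
  expect_lt(max(abs(cv$mean_curve - truth_sm)) / max(truth), 0.15)
  expect_lt(circ_dist(preferred_direction(cv), pop$preferred_deg[1]), 6)
})

test_that("tuning is invariant to global spike-amplitude rescaling", {
  tr <- fix_session(reps = 2, rots = 2, seed = 5)
  set.seed(6)
  s <- rpois(nrow(tr), 0.2)
  c1 <- tuning_curve(s, tr)$mean_curve
  c2 <- tuning_curve(3.7 * s, tr)$mean_curve
  expect_equal(c2, 3.7 * c1, tolerance = 1e-12)
})

test_that("cross-validated alignment sends peaks to the reference bin", {
  # identical trials peaked at bin 17
  base <- rep(0, 60); base[17] <- 5; base[16] <- base[18] <- 2
  P <- matrix(rep(base, 6), 6, byrow = TRUE)
  al <- crossval_align(P)
  ref <- 31
  for (i in 1:6) expect_equal(which.max(al$aligned[i, ]), ref)
  # jittered bumps: aligned dispersion does not exceed raw dispersion
  set.seed(7)
  bump <- 5 * exp(-(circ_diff(bin_centers(60), 100) / 25)^2)
  Pj <- t(vapply(1:8, function(i) {
    k <- sample(-1:1, 1)
    bump[((seq_len(60) - k - 1) %% 60) + 1] + rnorm(60, 0, 0.1)
  }, numeric(60)))
  alj <- crossval_align(Pj)
  disp <- function(m) {
    pk <- bin_centers(60)[apply(m, 1, which.max)]
    1 - rayleigh_vector_length(pk)
  }
  expect_lte(disp(alj$aligned), disp(Pj) + 1e-12)
  # companion matrices rotate by the overall light-on offset
  comp <- matrix(0, 6, 60)
  alc <- crossval_align(P, companion = comp)
  expect_equal(alc$companion_aligned, comp)
  comp2 <- matrix(rnorm(4 * 60), 4, 60)   # different trial count is fine
  alc2 <- crossval_align(P, companion = comp2)
  k <- alc2$overall_offset
  expect_equal(k, ref - 17)
  for (i in 1:4)
    expect_equal(alc2$companion_aligned[i, ],
                 comp2[i, ((seq_len(60) - k - 1) %% 60) + 1])
  expect_error(crossval_align(P[1, , drop = FALSE]), "at least 2")
})

test_that("per-trial curves mark unvisited bins missing and drop them from averages", {
  tr <- fix_session(reps = 2, rots = 2, seed = 8)
  # truncate one trial's frames artificially by blanking its trial id
  tr2 <- tr
  t1 <- which(!is.na(tr2$trial_id) & tr2$trial_id == 1)
  tr2$trial_id[t1[seq_len(length(t1) %/% 2)]] <- NA
  s <- rep(1, nrow(tr2))
  cv <- tuning_curve(s, tr2)
  expect_true(anyNA(cv$per_trial[1, ]))
  expect_false(anyNA(cv$mean_curve))
})
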