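test_that("delta phase offsets vanish for coherent shifts and flag dissenters", {
  set.seed(1)
  prefs <- runif(40, 0, 360)
  # common 90-degree shift cancels exactly
  res <- delta_phase_offset(prefs, (prefs - 90) %% 360)
  expect_equal(res$delta_phase_offset, rep(0, 40), tolerance = 1e-10)
  # one cell shifted 180 against a coherent population
  b <- (prefs - 90) %% 360
  b[7] <- (b[7] + 180) %% 360
  res2 <- delta_phase_offset(prefs, b)
  expect_equal(abs(res2$delta_phase_offset[7]), 180, tolerance = 1e-10)
  expect_lt(max(abs(res2$delta_phase_offset[-7])), 20)
  expect_error(delta_phase_offset(10, 20), "at least 2")
})

test_that("delta phase offset is invariant to common rotations of either context", {
  set.seed(2)
  a <- runif(25, 0, 360)
  b <- (a - runif(25, 0, 20)) %% 360   # mostly coherent with jitter
  base <- delta_phase_offset(a, b)$delta_phase_offset
  rot <- delta_phase_offset((a + 123) %% 360, (b + 301) %% 360)$delta_phase_offset
  expect_equal(rot, base, tolerance = 1e-8)
})

test_that("random independent shifts yield a near-uniform delta distribution", {
  set.seed(3)
  n <- 400
  a <- runif(n, 0, 360)
  b <- runif(n, 0, 360)
  d <- delta_phase_offset(a, b)$delta_phase_offset
  ks <- suppressWarnings(stats::ks.test(d, "punif", -180, 180))
  expect_gt(ks$p.value, 0.05)
  # shuffled-pair control on a coherent population is also near-uniform
  coh_a <- runif(n, 0, 360)
  coh_b <- (coh_a - 45) %% 360
  ds <- shuffled_pair_control(coh_a, coh_b, seed = 4)$delta_phase_offset
  ks2 <- suppressWarnings(stats::ks.test(ds, "punif", -180, 180))
  expect_gt(ks2$p.value, 0.05)
})

test_that("flip score closed forms hold on the 60-bin grid", {
  th <- bin_centers(60)
  f2 <- flip_score(cos(2 * th * pi / 180))
  expect_equal(f2$cc180, 1, tolerance = 1e-12)
  expect_equal(f2$cc90, -1, tolerance = 1e-12)
  expect_equal(f2$cc270, -1, tolerance = 1e-12)
  expect_equal(f2$flip, 2, tolerance = 1e-12)
  f1 <- flip_score(cos(th * pi / 180))
  expect_equal(f1$cc180, -1, tolerance = 1e-12)
  expect_equal(f1$flip, -1, tolerance = 1e-12)
  expect_equal(f1$cc90, 0, tolerance = 1e-12)
  # affine rescaling leaves the score unchanged
  y <- 2 + 0.5 * cos(2 * th * pi / 180) + 0.1 * cos(th * pi / 180)
  expect_equal(flip_score(y)$flip, flip_score(10 - 3 * y)$flip, tolerance = 1e-12)
  # degenerate flat curve
  fd <- flip_score(rep(2, 60))
  expect_true(fd$degenerate)
  expect_equal(fd$flip, 0)
})

test_that("landmark-cell light-on curves are more flip-symmetric than heading cells", {
  tr <- fix_session(reps = 4, rots = 3, seed = 5)
  pop <- fix_population(30, c(heading = 0.5, landmark = 0.5), seed = 6)
  sim <- simulate_traces(pop, tr, seed = 7)
  curves <- compute_tuning_curves(sim$spikes, tr, condition = "light_on")
  flips <- vapply(curves, function(cv) flip_score(cv)$flip, numeric(1))
  lm <- pop$class == "landmark"
  expect_gt(min(flips[lm]), max(flips[!lm]))
  expect_true(all(flips[lm] > 0))
})

test_that("flip-score group comparison is a one-way F-test", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(30)
  r <- compare_flip_scores(x, y)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 58)
  # equals the squared two-sample t statistic (equal variances)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  # identical groups: p ~ 1; separated means: tiny p
  expect_gt(compare_flip_scores(c(x, 1e-9), c(x, -1e-9))$p, 0.99)
  expect_lt(compare_flip_scores(rnorm(500), rnorm(500, 2))$p, 1e-3)
  expect_error(compare_flip_scores(rep(1, 5), rep(1, 5)), "degenerate")
})
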