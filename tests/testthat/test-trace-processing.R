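test_that("neuropil correction recovers the mixing fraction", {
  set.seed(1)
  n <- 3000
  np <- as.numeric(stats::filter(rnorm(n), 0.8, method = "recursive")) + 5
  s <- abs(rnorm(n))                      # independent somatic signal
  for (a_true in c(0.2, 0.5, 0.8)) {
    nc <- neuropil_correct(s + a_true * np, np)
    expect_lt(abs(nc$alpha - a_true), 0.03)
    # oracle: dense grid search over alpha
    grid <- seq(0, 1, by = 1e-3)
    ac <- vapply(grid, function(a)
      abs(cor(s + a_true * np - a * (np - mean(np)), np)), numeric(1))
    expect_lt(abs(nc$alpha - grid[which.min(ac)]), 2e-3)
  }
  # alpha always within [0, 1], even when the optimum lies outside
  nc2 <- neuropil_correct(s + 2 * np, np)
  expect_equal(nc2$alpha, 1)
  # constant neuropil: unchanged trace, zero alpha, warning
  expect_warning(nc3 <- neuropil_correct(s, rep(2, n)), "constant")
  expect_identical(nc3$F_corrected, s)
  expect_equal(nc3$alpha, 0)
})

test_that("dF/F uses the density mode as baseline", {
  expect_equal(compute_dff(rep(3, 100)),
               list(dff = rep(0, 100), F0 = 3))
  d <- compute_dff(c(rep(1, 499), 2))
  expect_equal(d$F0, 1, tolerance = 0.02)
  expect_equal(d$dff[500], 1, tolerance = 0.05)
  # bimodal density: mode at the heavy component, not the mean
  set.seed(2)
  x <- c(rnorm(800, 1, 0.05), rnorm(200, 3, 0.05))
  d2 <- compute_dff(x)
  expect_equal(d2$F0, 1, tolerance = 0.05)
  # oracle: kernel-density argmax
  kd <- stats::density(x, bw = "nrd0", n = 2048)
  expect_equal(d2$F0, kd$x[which.max(kd$y)])
  expect_error(compute_dff(c(rep(-5, 99), 1)), "F0")
})

test_that("dF/F is invariant to a common positive rescaling of the raw traces", {
  set.seed(3)
  n <- 2000
  np <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive")) + 10
  soma <- 2 + abs(rnorm(n)) + 0.4 * np
  run <- function(c_scale) {
    nc <- neuropil_correct(c_scale * soma, c_scale * np)
    compute_dff(nc$F_corrected)$dff
  }
  expect_equal(run(1), run(7.3), tolerance = 1e-6)
})

test_that("AR(1) deconvolution inverts the kernel and respects constraints", {
  gamma <- 0.85
  expect_equal(as.numeric(deconvolve_ar1(rep(0, 100), gamma = gamma)),
               rep(0, 100))
  # noiseless transient: single spike at onset
  y <- reconvolve_ar1(c(rep(0, 9), 1, rep(0, 40)), gamma)
  s <- deconvolve_ar1(y, gamma = gamma)
  expect_equal(which(s > 0), 10)
  expect_equal(s[10], 1)
  expect_error(deconvolve_ar1(rnorm(10), gamma = 1.2), "gamma")
  expect_error(deconvolve_ar1(rnorm(10), gamma = 0), "gamma")
  # inferred spikes track ground truth better than raw dff does
  set.seed(4)
  truth <- rpois(3000, 0.05)
  dff <- reconvolve_ar1(truth, 0.9) + rnorm(3000, 0, 0.05)
  s2 <- deconvolve_ar1(dff, gamma = 0.9)
  expect_gt(cor(s2, truth), cor(dff, truth))
  expect_true(all(s2 >= 0))
})

test_that("deconvolution residual shrinks as noise vanishes", {
  set.seed(5)
  truth <- rpois(2000, 0.05)
  resid_at <- function(sd) {
    dff <- reconvolve_ar1(truth, 0.9) + rnorm(2000, 0, sd)
    s <- deconvolve_ar1(dff, gamma = 0.9)
    mean((reconvolve_ar1(s, 0.9) - reconvolve_ar1(truth, 0.9))^2)
  }
  r <- vapply(c(0.2, 0.05, 0), resid_at, numeric(1))
  expect_true(all(diff(r) < 1e-9))
  expect_equal(r[3], 0, tolerance = 1e-12)
})

test_that("duplicate ROIs are removed one survivor per correlated component", {
  set.seed(6)
  base <- rnorm(500)
  # two identical traces -> one kept
  expect_length(deduplicate_rois(rbind(base, base)), 1)
  # independent traces all kept
  ind <- matrix(rnorm(5 * 500), 5)
  expect_length(deduplicate_rois(ind), 5)
  # chain A~B, B~C, A!~C: single survivor, the highest-variance member
  a <- rnorm(2000)
  b <- 0.65 * a + sqrt(1 - 0.65^2) * rnorm(2000)
  cc <- 0.65 * b + sqrt(1 - 0.65^2) * rnorm(2000)
  stopifnot(cor(a, b) > 0.5, cor(b, cc) > 0.5, cor(a, cc) < 0.5)
  m <- rbind(a, b, cc)
  kept <- deduplicate_rois(m)
  expect_length(kept, 1)
  expect_equal(kept, unname(which.max(apply(m, 1, var))))
  # oracle: brute force over all retained subsets of the 3-node graph
  adj <- cor(t(m)) > 0.5; diag(adj) <- FALSE
  valid <- Filter(function(ix) !any(adj[ix, ix]),
                  unlist(lapply(1:3, function(k) combn(3, k, simplify = FALSE)),
                         recursive = FALSE))
  max_size <- max(lengths(valid))
  expect_true(length(kept) <= max_size)
})
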