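# one classified synthetic population shared by the blocks below
fix_mix <- c(heading = 0.22, landmark = 0.33, alignment = 0.28) / 0.83
fix_tr <- generate_session(session_config(n_repeats = 4, rotation_duration = 96,
                                          seed = 22))
fix_pop <- generate_population(150, class_mix = fix_mix, peak_rate = 20,
                               baseline_rate = 0.5, noise_sd = 0.01, seed = 122)
fix_sim <- simulate_traces(fix_pop, fix_tr, seed = 222)
fix_cl <- classify_population(fix_sim$spikes, fix_tr, seed = 322)

test_that("silhouette selects three clusters for well-separated 3-class features", {
  set.seed(1)
  # feature-level oracle: three Gaussian blobs in the 8-d coefficient space
  blob <- function(m, n) sweep(matrix(rnorm(n * 8, 0, 0.04), n, 8), 2, m, "+")
  centers <- list(c(1, .35, 0, .30, .9, .35, 0, .30),      # unimodal/unimodal
                  c(1, .35, .7, .35, .05, .30, 0, .30),    # bimodal/flat
                  c(1, .35, .7, .35, .9, .35, 0, .30))     # bimodal/unimodal
  F <- do.call(rbind, Map(blob, centers, c(40, 60, 50)))
  colnames(F) <- c("a1_on", "c1_on", "a2_on", "c2_on",
                   "a1_off", "c1_off", "a2_off", "c2_off")
  F[, c(2, 4, 6, 8)] <- F[, c(2, 4, 6, 8)] * 100
  cl <- cluster_responses(F, seed = 2)
  expect_equal(cl$k_selected, 3)
  expect_equal(sort(as.integer(table(cl$cluster_ids[cl$cluster_ids > 0]))),
               sort(c(40L, 60L, 50L)), tolerance = 0.05)
  # the pipeline fixture also lands on k = 3 with a clear silhouette max
  expect_equal(fix_cl$clustering$k_selected, 3)
})

test_that("archetype semantics follow shape, and cells recover their class", {
  labs <- vapply(fix_cl$assignment$archetypes, `[[`, character(1), "label")
  expect_setequal(labs, c("heading", "landmark", "alignment"))
  tab <- table(factor(fix_pop$class,
                      levels = c("heading", "landmark", "alignment")),
               factor(fix_cl$assignment$label,
                      levels = c("heading", "landmark", "alignment", "null")))
  acc <- sum(diag(tab[, 1:3])) / nrow(fix_pop)
  expect_gte(acc, 0.9)
  # landmark archetype is more flip-symmetric than the heading archetype
  arch <- fix_cl$assignment$archetypes
  f_land <- flip_score(arch[[which(labs == "landmark")]]$curve_on)$flip
  f_head <- flip_score(arch[[which(labs == "heading")]]$curve_on)$flip
  expect_gt(f_land, f_head)
})

test_that("far outliers are sent to the null cluster", {
  feats <- fix_cl$features$features[fix_cl$features$ok, , drop = FALSE]
  # a cell far from every fitted centroid (amplitudes ~unit scale,
  # widths ~100-degree scale) is evaluated into the null cluster
  out <- matrix(colMeans(feats) +
                  ifelse(startsWith(colnames(feats), "c"), 800, 8), 1,
                dimnames = list(NULL, colnames(feats)))
  expect_equal(classify_new_cells(fix_cl$clustering, out), 0L)
  # typical members stay in their own clusters under evaluation
  ids_in <- fix_cl$clustering$cluster_ids[fix_cl$features$ok]
  re <- classify_new_cells(fix_cl$clustering, feats)
  expect_gt(mean(re[ids_in > 0] == ids_in[ids_in > 0]), 0.95)
})

test_that("cluster membership is stable across mixture seeds", {
  feats <- fix_cl$features$features[fix_cl$features$ok, , drop = FALSE]
  c1 <- cluster_responses(feats, seed = 1)
  c2 <- cluster_responses(feats, seed = 99)
  expect_equal(c1$k_selected, c2$k_selected)
  # adjusted agreement between the two partitions (mclust's ARI)
  ari <- mclust::adjustedRandIndex(c1$cluster_ids, c2$cluster_ids)
  expect_gt(ari, 0.95)
})

test_that("LDA projection separates classes and is deterministic", {
  feats <- fix_cl$features$features
  labs <- fix_cl$assignment$label
  p1 <- lda_project(feats, labs)
  p2 <- lda_project(feats, labs)
  expect_identical(p1$coords, p2$coords)
  keep <- labs != "null" & stats::complete.cases(feats)
  co <- p1$coords[keep, , drop = FALSE]
  g <- labs[keep]
  centers <- rowsum(co, g) / as.vector(table(g))
  between <- sum(stats::dist(centers)^2)
  within <- mean(vapply(unique(g), function(cl) {
    m <- co[g == cl, , drop = FALSE]
    mean(rowSums(sweep(m, 2, colMeans(m))^2))
  }, numeric(1)))
  expect_gt(between / within, 5)
  # projecting held-out data with the trained model works
  pn <- lda_project(feats, labs, newdata = feats[1:5, , drop = FALSE])
  expect_equal(dim(pn$new_coords), c(5, 2))
  expect_error(lda_project(feats, rep("heading", length(labs))), "2 labelled")
})

test_that("degenerate feature matrices are rejected", {
  expect_error(cluster_responses(matrix(1, 40, 4,
                                        dimnames = list(NULL, c("a1", "c1", "a2", "c2")))),
               "degenerate")
  expect_error(cluster_responses(fix_cl$features$features[1:10, ]), "at least 30")
})
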