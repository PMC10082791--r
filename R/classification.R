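#' Build per-cell Gaussian-fit feature vectors for clustering
#'
#' For each cell: the light-on per-trial curves are cross-validation aligned
#' (peak to the reference bin) and the identical offsets applied to the
#' light-off trials; both trial-averaged curves are normalised by the peak of
#' the light-on average (one common scale, so a class whose response
#' collapses in darkness keeps a small light-off amplitude); a two-term sum
#' of Gaussians is fit to each condition. The clustering feature vector is
#' `(a1, c1, a2, c2)` light-on followed by light-off — 8 dimensions, with the
#' location coefficients deliberately excluded so preferred direction cannot
#' drive cluster membership.
#'
#' Because the free two-term fit is unidentifiable when a curve holds only
#' one bump (the second term can shadow the first or model baseline
#' structure with an arbitrary width), coefficients are canonicalised before
#' entering the feature vector: a second term counts as a genuine second
#' peak only if its amplitude exceeds `min_amp` (on the normalised scale),
#' its location is at least `min_sep` degrees from the first peak, and its
#' width is at most `max_width` degrees (wider terms model baseline, not a
#' peak); otherwise the curve is refit with one term, `a2` set to 0, and the
#' undefined width replaced by the neutral value `neutral_c` (the width of
#' an absent peak carries no information). A first term that is itself
#' baseline-like (amplitude below `min_amp`, or width above `max_width`) has
#' its width neutralised too, and a baseline-wide first term its amplitude
#' zeroed.
#'
#' @param curves_on,curves_off lists of `tuning_curve` objects (same cells).
#' @param min_amp minimum amplitude for a peak to be real (default 0.1 of
#'   the light-on peak).
#' @param min_sep minimum separation of two genuine peaks in degrees
#'   (default 60).
#' @param max_width maximum width of a genuine peak in degrees (default 120).
#' @param neutral_c width recorded for an absent peak, degrees (default 30).
#' @return list with `features` (n x 8 matrix), `fits_on`, `fits_off`
#'   (per-cell [fit_sum_of_gaussians()] results), `curve_on`, `curve_off`
#'   (n x 60 aligned normalised mean curves), `ok` (cells with converged
#'   fits in both conditions).
#' @export
classification_features <- function(curves_on, curves_off,
                                    min_amp = 0.1, min_sep = 60,
                                    max_width = 120, neutral_c = 30) {
  stopifnot(length(curves_on) == length(curves_off))
  n <- length(curves_on)
  n_bins <- length(curves_on[[1]]$mean_curve)
  canonical <- function(fit, y) {
    co <- fit$coef
    if (!fit$converged || anyNA(co[c("a1", "c1")])) return(fit)
    second_real <- !is.na(co[["b2"]]) && co[["a2"]] >= min_amp &&
      circ_dist(co[["b1"]], co[["b2"]]) >= min_sep && co[["c2"]] <= max_width
    if (!second_real) {
      f1 <- fit_sum_of_gaussians(y, n_terms = 1)
      if (f1$converged) fit <- f1
      fit$coef[c("a2", "c2")] <- c(0, neutral_c)
      fit$coef["b2"] <- NA_real_
    }
    if (fit$coef[["c1"]] > max_width) fit$coef["a1"] <- 0
    if (fit$coef[["a1"]] < min_amp || fit$coef[["c1"]] > max_width)
      fit$coef["c1"] <- neutral_c
    fit
  }
  feat <- matrix(NA_real_, n, 8,
                 dimnames = list(NULL, c("a1_on", "c1_on", "a2_on", "c2_on",
                                         "a1_off", "c1_off", "a2_off", "c2_off")))
  con <- coff <- matrix(NA_real_, n, n_bins)
  fits_on <- fits_off <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    al <- crossval_align(curves_on[[i]]$per_trial,
                         companion = curves_off[[i]]$per_trial)
    m_on <- colMeans(al$aligned, na.rm = TRUE)
    m_off <- colMeans(al$companion_aligned, na.rm = TRUE)
    pk <- max(m_on, na.rm = TRUE)
    if (!is.finite(pk) || pk <= 0) next
    m_on <- m_on / pk; m_off <- m_off / pk
    f_on <- canonical(fit_sum_of_gaussians(m_on, n_terms = 2), m_on)
    f_off <- canonical(fit_sum_of_gaussians(m_off, n_terms = 2), m_off)
    fits_on[[i]] <- f_on; fits_off[[i]] <- f_off
    con[i, ] <- m_on; coff[i, ] <- m_off
    if (f_on$converged && f_off$converged) {
      feat[i, ] <- c(f_on$coef[c("a1", "c1", "a2", "c2")],
                     f_off$coef[c("a1", "c1", "a2", "c2")])
      ok[i] <- all(is.finite(feat[i, ]))
    }
  }
  list(features = feat, fits_on = fits_on, fits_off = fits_off,
       curve_on = con, curve_off = coff, ok = ok)
}

#' Gaussian-mixture clustering of fit-coefficient features
#'
#' Fits Gaussian mixtures over a range of component numbers, selects k by the
#' mean silhouette width of the resulting hard partition, and flags outliers:
#' cells whose minimum squared Mahalanobis distance to any component exceeds
#' the chi-square `outlier_q` quantile (df = feature dimension) are assigned
#' the null cluster (id 0).
#'
#' Distances mix amplitude coefficients (normalised response units, order 1)
#' and width coefficients (degrees, order tens). The default `"natural"`
#' scaling divides width columns (names starting with `"c"`) by 100 so both
#' families live on a comparable ~unit scale while keeping their real
#' variances — a pure-noise dimension stays small instead of being inflated
#' to unit variance as z-scoring (`"zscore"`) would do. `means` are reported
#' on the original scale.
#'
#' @param features n x d numeric matrix (n >= 30) with named columns.
#' @param k_range candidate cluster numbers (default 2:8).
#' @param outlier_q chi-square quantile for the null-cluster rule
#'   (default 0.99).
#' @param scaling `"natural"`, `"zscore"`, or `"none"`.
#' @param seed seed for the mixture fits.
#' @return list of class `gmm_clustering`: `cluster_ids` (0 = null),
#'   `k_selected`, `silhouette` (named by k), `means`, `covariances`,
#'   `proportions`, `mahalanobis_min`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_responses <- function(features, k_range = 2:8, outlier_q = 0.99,
                              scaling = c("natural", "zscore", "none"),
                              seed = 1L) {
  scaling <- match.arg(scaling)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 30L) stop("need at least 30 cells to cluster")
  # constant columns (e.g. no cell has a second dark peak) carry no cluster
  # information and break scaling; cluster on the informative ones
  keep_col <- apply(features, 2, stats::sd) > .Machine$double.eps^0.5
  if (sum(keep_col) < 2L)
    stop("degenerate features: fewer than 2 columns with variance")
  feats_used <- features[, keep_col, drop = FALSE]
  d <- ncol(feats_used)
  set.seed(seed)
  ctr <- rep(0, d)
  scl <- switch(scaling,
    natural = ifelse(startsWith(colnames(feats_used), "c"), 100, 1),
    zscore = { ctr <- colMeans(feats_used); apply(feats_used, 2, stats::sd) },
    none = rep(1, d))
  z <- sweep(sweep(feats_used, 2, ctr), 2, scl, "/")
  dmat <- stats::dist(z)
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(z, G = k, verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$classification)) < 2L) next
    fits[[j]] <- fit
    sil[j] <- mean(cluster::silhouette(fit$classification, dmat)[, "sil_width"])
  }
  if (all(is.na(sil))) stop("mixture fitting failed for every k")
  k_sel <- k_range[which.max(sil)]
  fit <- fits[[which.max(sil)]]
  means_z <- t(fit$parameters$mean)
  covs <- lapply(seq_len(k_sel), function(g) {
    S <- if (length(dim(fit$parameters$variance$sigma)) == 3)
      fit$parameters$variance$sigma[, , g] else fit$parameters$variance$Sigma
    S + diag(1e-8, d)
  })
  d2 <- sapply(seq_len(k_sel), function(g)
    stats::mahalanobis(z, means_z[g, ], covs[[g]]))
  d2 <- matrix(d2, nrow = n)
  min_d2 <- apply(d2, 1, min)
  ids <- fit$classification
  ids[min_d2 > stats::qchisq(outlier_q, df = d)] <- 0L
  means_used <- sweep(sweep(means_z, 2, scl, "*"), 2, ctr, "+")
  # report means on the full feature layout, constant columns at their value
  means <- matrix(rep(colMeans(features), each = k_sel), k_sel,
                  ncol(features), dimnames = list(NULL, colnames(features)))
  means[, keep_col] <- means_used
  structure(list(cluster_ids = ids, k_selected = k_sel, silhouette = sil,
                 means = means, covariances = covs,
                 center = ctr, scale = scl, used_columns = which(keep_col),
                 proportions = fit$parameters$pro,
                 mahalanobis_min = sqrt(min_d2)),
            class = "gmm_clustering")
}

#' Assign cells to fitted mixture clusters, with the null-outlier rule
#'
#' Evaluates new (or held-out) feature vectors against an existing
#' [cluster_responses()] fit: each cell goes to the component with the
#' smallest Mahalanobis distance, or to the null cluster (0) when that
#' minimum exceeds the chi-square `outlier_q` quantile.
#'
#' @param clustering a `gmm_clustering`.
#' @param features matrix with the same columns the clustering was fit on.
#' @param outlier_q chi-square quantile (default 0.99, as in fitting).
#' @return integer cluster ids (0 = null).
#' @export
classify_new_cells <- function(clustering, features, outlier_q = 0.99) {
  features <- as.matrix(features)
  cols <- clustering$used_columns
  z <- sweep(sweep(features[, cols, drop = FALSE], 2, clustering$center),
             2, clustering$scale, "/")
  means_z <- sweep(sweep(clustering$means[, cols, drop = FALSE], 2,
                         clustering$center), 2, clustering$scale, "/")
  d2 <- sapply(seq_len(nrow(means_z)), function(g)
    stats::mahalanobis(z, means_z[g, ], clustering$covariances[[g]]))
  d2 <- matrix(d2, nrow = nrow(z))
  ids <- apply(d2, 1, which.min)
  ids[apply(d2, 1, min) > stats::qchisq(outlier_q, df = ncol(z))] <- 0L
  as.integer(ids)
}

#' @export
print.gmm_clustering <- function(x, ...) {
  cat(sprintf("gmm_clustering: k = %d selected by silhouette (%d null-cluster cells)\n",
              x$k_selected, sum(x$cluster_ids == 0L)))
  print(round(x$silhouette, 3))
  invisible(x)
}

# semantic label of one archetype from its shape:
# bimodal light-on + collapsed light-off -> landmark;
# bimodal light-on + retained unimodal light-off -> alignment;
# otherwise (unimodal both) -> heading.
archetype_label <- function(co_on, co_off,
                            bimodal_ratio = 0.5, flat_amp = 0.35) {
  bimodal_on <- co_on[["a1"]] > 0 && co_on[["a2"]] / co_on[["a1"]] > bimodal_ratio
  off_amp <- co_off[["a1"]]
  if (bimodal_on && off_amp < flat_amp) "landmark"
  else if (bimodal_on) "alignment"
  else "heading"
}

#' Assign functional classes via archetypal tuning curves
#'
#' Archetypal light-on and light-off curves are reconstructed per cluster
#' from the cluster-mean fit coefficients (first peak at the reference bin,
#' second at its antipode). Each cell is labelled by the archetype with the
#' smallest summed cosine distance (light-on + light-off) to its aligned
#' normalised curves. Because the dual-cue environment is 180-degree
#' symmetric, a cell's surviving dark peak may sit at either light-on peak;
#' the light-off distance is therefore the minimum over the archetype curve
#' and its 180-degree rotation. Archetype semantics (heading / landmark / alignment)
#' are decided by measurable shape criteria — the light-on bimodality ratio
#' `a2/a1` and the light-off amplitude — never by cluster index. Cells in the
#' null cluster keep the label `"null"`.
#'
#' @param feats output of [classification_features()].
#' @param clustering output of [cluster_responses()] on `feats$features`.
#' @param ref_deg reference peak location in degrees (default the middle bin
#'   centre, 183 on the 60-bin grid).
#' @return list of class `class_assignment`: `label` (per cell),
#'   `cluster_id`, `cosine_dists` (n x k), `archetypes` (per cluster: label,
#'   coefficients, curves), `mahalanobis_min`.
#' @export
assign_classes <- function(feats, clustering, ref_deg = 183) {
  k <- clustering$k_selected
  n_bins <- ncol(feats$curve_on)
  bc <- bin_centers_deg(n_bins)
  arch <- vector("list", k)
  for (g in seq_len(k)) {
    m <- clustering$means[g, ]
    members <- clustering$cluster_ids == g
    a0_on <- mean(vapply(feats$fits_on[members], function(f)
      f$coef[["a0"]], numeric(1)), na.rm = TRUE)
    a0_off <- mean(vapply(feats$fits_off[members], function(f)
      f$coef[["a0"]], numeric(1)), na.rm = TRUE)
    co_on <- c(a0 = a0_on, a1 = m[["a1_on"]], b1 = ref_deg, c1 = m[["c1_on"]],
               a2 = m[["a2_on"]], b2 = wrap360(ref_deg + 180), c2 = m[["c2_on"]])
    co_off <- c(a0 = a0_off, a1 = m[["a1_off"]], b1 = ref_deg, c1 = m[["c1_off"]],
                a2 = m[["a2_off"]], b2 = wrap360(ref_deg + 180), c2 = m[["c2_off"]])
    arch[[g]] <- list(
      label = archetype_label(co_on, co_off),
      coef_on = co_on, coef_off = co_off,
      curve_on = eval_sum_of_gaussians(co_on, bc),
      curve_off = eval_sum_of_gaussians(co_off, bc))
  }
  cosine_dist <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    nx <- sqrt(sum(x[ok]^2)); ny <- sqrt(sum(y[ok]^2))
    if (nx == 0 || ny == 0) return(1)
    1 - sum(x[ok] * y[ok]) / (nx * ny)
  }
  n <- nrow(feats$curve_on)
  half <- n_bins %/% 2L
  dists <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    if (!feats$ok[i]) next
    for (g in seq_len(k)) {
      d_off <- min(cosine_dist(feats$curve_off[i, ], arch[[g]]$curve_off),
                   cosine_dist(feats$curve_off[i, ],
                               circ_shift(arch[[g]]$curve_off, half)))
      dists[i, g] <- cosine_dist(feats$curve_on[i, ], arch[[g]]$curve_on) + d_off
    }
  }
  label <- rep("null", n)
  assignable <- feats$ok & clustering$cluster_ids != 0L
  best <- apply(dists, 1, function(r) if (all(is.na(r))) NA_integer_ else which.min(r))
  label[assignable] <- vapply(best[assignable], function(g) arch[[g]]$label,
                              character(1))
  structure(list(label = label, cluster_id = clustering$cluster_ids,
                 cosine_dists = dists, archetypes = arch,
                 mahalanobis_min = clustering$mahalanobis_min),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat("class_assignment:\n")
  print(table(x$label))
  invisible(x)
}

#' Linear-discriminant projection of fit features for visualisation
#'
#' Trains an LDA on the labelled feature vectors and returns the first two
#' discriminant coordinates (zero-padded when only one discriminant exists).
#' The projection is for visualisation only — class membership comes from
#' [assign_classes()].
#'
#' @param features n x d matrix.
#' @param labels class labels (>= 2 distinct, non-null).
#' @param newdata optional matrix to project with the trained model (e.g.
#'   axonal features).
#' @return list with `coords` (n x 2), `model`, and `new_coords` when
#'   `newdata` was given.
#' @export
lda_project <- function(features, labels, newdata = NULL) {
  features <- as.matrix(features)
  keep <- !is.na(labels) & labels != "null" & stats::complete.cases(features)
  if (length(unique(labels[keep])) < 2L)
    stop("LDA projection needs at least 2 labelled classes")
  g <- factor(labels[keep])
  x <- features[keep, , drop = FALSE]
  # columns constant within every group contribute nothing and break lda
  within_sd <- vapply(seq_len(ncol(x)), function(j)
    sqrt(mean(tapply(x[, j], g, stats::var), na.rm = TRUE)), numeric(1))
  cols <- which(is.finite(within_sd) & within_sd > 1e-8)
  if (length(cols) < 1L) stop("no informative feature columns for LDA")
  model <- MASS::lda(x = x[, cols, drop = FALSE], grouping = g)
  proj <- function(m) {
    p <- stats::predict(model, m[, cols, drop = FALSE])$x
    if (ncol(p) == 1L) p <- cbind(p, 0)
    p[, 1:2, drop = FALSE]
  }
  coords <- matrix(NA_real_, nrow(features), 2)
  coords[keep, ] <- proj(x)
  out <- list(coords = coords, model = model, columns = cols)
  if (!is.null(newdata)) out$new_coords <- proj(as.matrix(newdata))
  out
}

#' End-to-end functional classification of a population
#'
#' Convenience wrapper: builds light-on/light-off tuning curves from spikes
#' and tracking, extracts fit features, clusters, and assigns class labels.
#'
#' @param spikes cells x frames activity matrix (inferred spikes).
#' @param track tracking series with both light conditions.
#' @param k_range,outlier_q,seed passed to [cluster_responses()].
#' @return list with `curves_on`, `curves_off`, `features` (the
#'   [classification_features()] output), `clustering`, `assignment`.
#' @export
classify_population <- function(spikes, track, k_range = 2:8,
                                outlier_q = 0.99, seed = 1L) {
  curves_on <- compute_tuning_curves(spikes, track, condition = "light_on")
  curves_off <- compute_tuning_curves(spikes, track, condition = "light_off")
  feats <- classification_features(curves_on, curves_off)
  clustering <- cluster_responses(feats$features[feats$ok, , drop = FALSE],
                                  k_range = k_range, outlier_q = outlier_q,
                                  seed = seed)
  # re-embed cluster ids for dropped cells as null
  ids <- rep(0L, length(curves_on))
  ids[feats$ok] <- clustering$cluster_ids
  clustering_full <- clustering
  clustering_full$cluster_ids <- ids
  assignment <- assign_classes(feats, clustering_full)
  list(curves_on = curves_on, curves_off = curves_off, features = feats,
       clustering = clustering_full, assignment = assignment)
}
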