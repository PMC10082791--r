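#' Coherent-remapping statistic (delta phase offset)
#'
#' For each cell, its phase offset is the circular difference between its
#' preferred direction in context A and context B. The delta phase offset
#' subtracts the population's expected offset, estimated from all other cells
#' (leave-one-out): a population that rotates rigidly between contexts gives
#' delta = 0 for every cell, whatever the rotation.
#'
#' Two aggregation variants are provided. The default, `"offset_median"`,
#' takes the circular median of the leave-one-out per-cell offsets
#' (difference-then-aggregate), which is invariant to a common rotation of
#' either context. `"pref_median"` takes the difference of the circular
#' medians of the leave-one-out preferred directions in each context
#' (aggregate-then-difference).
#'
#' @param prefs_A,prefs_B preferred directions (degrees) of the same cells in
#'   contexts A and B (>= 2 cells).
#' @param method `"offset_median"` or `"pref_median"`.
#' @return data frame with `pref_A`, `pref_B`, `phase_offset`,
#'   `delta_phase_offset` (all signed degrees in (-180, 180] where applicable).
#' @export
delta_phase_offset <- function(prefs_A, prefs_B,
                               method = c("offset_median", "pref_median")) {
  method <- match.arg(method)
  stopifnot(length(prefs_A) == length(prefs_B))
  n <- length(prefs_A)
  if (n < 2L) stop("delta phase offset needs at least 2 cells")
  off <- circ_diff(prefs_A, prefs_B)
  delta <- if (method == "offset_median") {
    circ_diff(off, circ_median_loo(off))
  } else {
    vapply(seq_len(n), function(i)
      circ_diff(off[i], circ_diff(circ_median(prefs_A[-i]),
                                  circ_median(prefs_B[-i]))), numeric(1))
  }
  data.frame(pref_A = wrap360(prefs_A), pref_B = wrap360(prefs_B),
             phase_offset = off, delta_phase_offset = delta)
}

#' Shuffled-pair control for the delta-phase-offset analysis
#'
#' Re-pairs cells at random across the two contexts before computing the
#' delta phase offsets, destroying true cell identity; a coherent population
#' yields a near-uniform control distribution.
#'
#' @param prefs_A,prefs_B preferred directions as in [delta_phase_offset()].
#' @param seed seed for the permutation.
#' @return data frame as from [delta_phase_offset()].
#' @export
shuffled_pair_control <- function(prefs_A, prefs_B, seed = 1L) {
  set.seed(seed)
  delta_phase_offset(prefs_A, prefs_B[sample(length(prefs_B))])
}

#' Flip score: bimodality of a tuning curve
#'
#' Circular autocorrelation (Pearson correlation between the curve and its
#' circular shift) evaluated at 180, 90 and 270 degrees;
#' `flip = CC180 - (CC90 + CC270) / 2`. On the 60-bin grid the lags are
#' exactly 30, 15 and 45 bins. A strongly bimodal (cue-symmetric) curve has a
#' large positive flip score; a unimodal curve does not.
#'
#' @param curve a `tuning_curve` or numeric curve whose length is divisible
#'   by 4.
#' @return list of class `flip_score`: `cc180`, `cc90`, `cc270`, `flip`,
#'   `degenerate` (TRUE for a zero-variance curve, where flip is defined 0).
#' @export
flip_score <- function(curve) {
  y <- if (inherits(curve, "tuning_curve")) curve$mean_curve else curve
  y <- as.numeric(y)
  n <- length(y)
  if (n %% 4L != 0L) stop("curve length must be divisible by 4")
  if (anyNA(y)) stop("curve contains missing bins")
  if (stats::var(y) < .Machine$double.eps) {
    return(structure(list(cc180 = NA_real_, cc90 = NA_real_, cc270 = NA_real_,
                          flip = 0, degenerate = TRUE), class = "flip_score"))
  }
  cc <- function(lag_bins) stats::cor(y, circ_shift(y, lag_bins))
  cc180 <- cc(n %/% 2L); cc90 <- cc(n %/% 4L); cc270 <- cc(3L * (n %/% 4L))
  structure(list(cc180 = cc180, cc90 = cc90, cc270 = cc270,
                 flip = cc180 - (cc90 + cc270) / 2, degenerate = FALSE),
            class = "flip_score")
}

#' @export
print.flip_score <- function(x, ...) {
  cat(sprintf("flip_score: %.3f (CC180 %.3f, CC90 %.3f, CC270 %.3f)%s\n",
              x$flip, x$cc180, x$cc90, x$cc270,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' One-way F-test between two groups of flip scores
#'
#' Variance-ratio (one-way ANOVA) test of equal means between two conditions,
#' with degrees of freedom (1, n1 + n2 - 2).
#'
#' @param group_on,group_off numeric vectors (>= 2 values each).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
compare_flip_scores <- function(group_on, group_off) {
  if (length(group_on) < 2L || length(group_off) < 2L)
    stop("need at least 2 values per group")
  y <- c(group_on, group_off)
  if (stats::var(y) < .Machine$double.eps)
    stop("degenerate variance: all flip scores identical")
  g <- factor(rep(c("on", "off"), c(length(group_on), length(group_off))))
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a[["F value"]][1], df1 = a[["Df"]][1], df2 = a[["Df"]][2],
       p = a[["Pr(>F)"]][1])
}
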