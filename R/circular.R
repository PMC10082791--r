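#' Circular helpers (degrees)
#'
#' Small circular-statistics toolkit used throughout the package. All angles
#' are in degrees; signed differences are mapped to (-180, 180].
#'
#' @name circular-helpers
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to [0, 360)
#' @param x angles in degrees.
#' @return angles in [0, 360).
#' @export
wrap360 <- function(x) x %% 360

#' Signed circular difference a - b, mapped to (-180, 180]
#' @param a,b angles in degrees.
#' @return signed differences in (-180, 180].
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Absolute circular distance in [0, 180]
#' @param a,b angles in degrees.
#' @return distances in [0, 180].
#' @export
circ_dist <- function(a, b) abs(circ_diff(a, b))

#' Circular mean of angles (degrees), optionally weighted
#' @param x angles in degrees.
#' @param w nonnegative weights.
#' @return mean direction in [0, 360); NA if resultant is 0.
#' @export
circ_mean <- function(x, w = NULL) {
  if (length(x) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(x))
  th <- deg2rad(x)
  C <- sum(w * cos(th)); S <- sum(w * sin(th))
  if (sqrt(C^2 + S^2) < .Machine$double.eps * sum(w)) return(NA_real_)
  wrap360(rad2deg(atan2(S, C)))
}

#' Mean resultant length of a set of angles or a nonnegative circular weight
#' function
#'
#' With only `x`, the classical Rayleigh mean resultant length of the sample.
#' With weights `w` (e.g. a tuning curve evaluated at bin centres `x`), the
#' resultant of the weight function: 0 for a flat curve, 1 for a delta.
#'
#' @param x angles in degrees.
#' @param w optional nonnegative weights (e.g. firing rates per bin).
#' @return a value in [0, 1]; NA if the total weight is 0.
#' @export
rayleigh_vector_length <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x))
  tot <- sum(w)
  if (length(x) == 0L || tot <= 0) return(NA_real_)
  th <- deg2rad(x)
  sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / tot
}

#' Circular median
#'
#' Minimiser of the mean circular absolute deviation, searched over the data
#' angles themselves; ties are resolved by the circular mean of all minimisers.
#'
#' @param x angles in degrees.
#' @return median direction in [0, 360).
#' @export
circ_median <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(wrap360(x))
  dev <- vapply(x, function(m) mean(circ_dist(x, m)), numeric(1))
  best <- which(dev <= min(dev) + 1e-10)
  if (length(best) == 1L) wrap360(x[best]) else circ_mean(x[best])
}

#' V-test for circular non-uniformity against a specified direction
#'
#' Tests whether angles are clustered around a hypothesised mean direction
#' `mu0`. The statistic is `V = n * Rbar * cos(theta_bar - mu0)` (the resultant
#' projected onto `mu0`); the p-value uses the normal approximation of
#' `u = V * sqrt(2 / n)` (one-sided).
#'
#' @param angles angles in degrees (n >= 2).
#' @param mu0 hypothesised mean direction in degrees.
#' @return list with `V`, `u`, `p`, `n`, `mu0`.
#' @export
v_test <- function(angles, mu0 = 0) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 2L) stop("v_test requires at least 2 angles")
  th <- deg2rad(angles)
  C <- mean(cos(th)); S <- mean(sin(th))
  rbar <- sqrt(C^2 + S^2)
  theta_bar <- atan2(S, C)
  V <- n * rbar * cos(theta_bar - deg2rad(mu0))
  u <- V * sqrt(2 / n)
  list(V = V, u = u, p = stats::pnorm(u, lower.tail = FALSE), n = n, mu0 = mu0)
}

# Leave-one-out circular medians of x, with a stability anchor: when the
# deviation objective has near-tied minimisers (within the influence one
# removed point can exert), the candidate closest to the full-sample median
# is taken. On concentrated data the anchor is inert; on near-uniform data it
# prevents the leave-one-out median from flipping between distant minimisers
# in a way that correlates with the removed point.
circ_median_loo <- function(x) {
  n <- length(x)
  if (n < 2L) stop("leave-one-out median needs at least 2 values")
  D <- abs(outer(x, x, circ_diff))         # |d(candidate j, point i)|
  tot <- colSums(D)                        # deviation sums over all points
  m0 <- circ_median(x)
  tol <- 2 * 180 / (n - 1)
  vapply(seq_len(n), function(i) {
    dev <- (tot - D[i, ]) / (n - 1)        # LOO objective at candidates = x
    dev[i] <- Inf                          # candidate must come from x[-i]
    near <- which(dev <= min(dev) + tol)
    x[near[which.min(circ_dist(x[near], m0))]]
  }, numeric(1))
}

# circularly shift a vector by k positions (positive k moves content rightward)
circ_shift <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

# unwrap a wrapped heading series into a continuous angle
unwrap_deg <- function(h) {
  if (length(h) <= 1L) return(h)
  d <- circ_diff(h[-1L], h[-length(h)])
  h[1L] + c(0, cumsum(d))
}
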