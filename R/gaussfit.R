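#' Fit a one- or two-term Gaussian to a heading tuning curve
#'
#' Nonlinear least-squares fit of
#' `f(x) = a0 + a1 exp(-((x - b1)/c1)^2) + a2 exp(-((x - b2)/c2)^2)`
#' (the second term only when `n_terms = 2`), with the angular difference
#' `x - b` evaluated circularly so peaks near the domain edge are handled
#' without artifacts. Coefficients are bounded (`a1, a2 >= 0`, `c1, c2 > 0`).
#' Fitting profiles the amplitudes (linear given locations and widths) over a
#' small grid of starts — peak 1 at the curve maximum, peak 2 at the antipode
#' or at the largest far-field value — and polishes the best candidate with
#' bounded Levenberg-Marquardt.
#'
#' @param y curve values (length-60 tuning curve typically).
#' @param x angles of the samples in degrees; default bin centres.
#' @param n_terms 1 or 2 Gaussian terms.
#' @param circular evaluate `x - b` as a circular difference (default TRUE).
#' @return list with `coef` (named: a0, a1, b1, c1, a2, b2, c2 — absent terms
#'   are 0/NA), `r2`, `fitted`, `converged`.
#' @export
fit_sum_of_gaussians <- function(y, x = bin_centers_deg(length(y)),
                                 n_terms = 2, circular = TRUE) {
  stopifnot(n_terms %in% 1:2, length(x) == length(y))
  ok <- !is.na(y)
  xv <- x[ok]; yv <- y[ok]
  empty <- list(coef = c(a0 = NA_real_, a1 = NA_real_, b1 = NA_real_,
                         c1 = NA_real_, a2 = 0, b2 = NA_real_, c2 = NA_real_),
                r2 = NA_real_, fitted = rep(NA_real_, length(y)),
                converged = FALSE)
  if (length(yv) < 3L + 3L * n_terms) return(empty)
  ss_tot <- sum((yv - mean(yv))^2)
  if (ss_tot < .Machine$double.eps) {
    out <- empty
    out$coef[c("a0", "a1", "a2")] <- c(mean(yv), 0, 0)
    out$r2 <- 0; out$fitted <- rep(mean(yv), length(y)); out$converged <- TRUE
    return(out)
  }
  dist_fun <- if (circular) function(x, b) circ_diff(x, b) else function(x, b) x - b
  model <- if (n_terms == 1L) {
    function(p) p["a0"] + p["a1"] * exp(-(dist_fun(xv, p["b1"]) / p["c1"])^2)
  } else {
    function(p) p["a0"] + p["a1"] * exp(-(dist_fun(xv, p["b1"]) / p["c1"])^2) +
      p["a2"] * exp(-(dist_fun(xv, p["b2"]) / p["c2"])^2)
  }
  resid_fun <- function(p) yv - model(p)
  b1_0 <- xv[which.max(yv)]
  amp <- max(yv) - min(yv)
  # profile stage: amplitudes are linear given (b, c); solve them over a
  # coarse width grid, dropping a negative bump amplitude and refitting
  profile_sse <- function(b1, c1, b2 = NA, c2 = NA) {
    X <- cbind(1, exp(-(dist_fun(xv, b1) / c1)^2))
    if (!is.na(b2)) X <- cbind(X, exp(-(dist_fun(xv, b2) / c2)^2))
    a <- tryCatch(stats::.lm.fit(X, yv)$coefficients, error = function(e) NULL)
    if (is.null(a)) return(NULL)
    if (any(a[-1] < 0)) {
      keep <- c(TRUE, a[-1] >= 0)
      a2 <- rep(0, length(a))
      a2[keep] <- stats::.lm.fit(X[, keep, drop = FALSE], yv)$coefficients
      a <- a2
    }
    list(a = a, sse = sum((yv - X %*% a)^2))
  }
  c_grid <- c(15, 30, 55)
  cand <- list()
  if (n_terms == 1L) {
    for (c1 in c(c_grid, 80)) {
      pr <- profile_sse(b1_0, c1)
      if (!is.null(pr))
        cand[[length(cand) + 1]] <- list(
          par = c(a0 = pr$a[1], a1 = max(pr$a[2], 0), b1 = b1_0, c1 = c1),
          sse = pr$sse)
    }
    lower <- c(a0 = -Inf, a1 = 0, b1 = -Inf, c1 = 1)
    upper <- c(a0 = Inf, a1 = Inf, b1 = Inf, c1 = 360)
  } else {
    far <- circ_dist(xv, b1_0) > 60
    b2_alt <- if (any(far)) xv[far][which.max(yv[far])] else wrap360(b1_0 + 180)
    for (c1 in c_grid) for (c2 in c_grid)
      for (b2 in unique(c(wrap360(b1_0 + 180), b2_alt))) {
        pr <- profile_sse(b1_0, c1, b2, c2)
        if (!is.null(pr))
          cand[[length(cand) + 1]] <- list(
            par = c(a0 = pr$a[1], a1 = max(pr$a[2], 0), b1 = b1_0, c1 = c1,
                    a2 = max(pr$a[3], 0), b2 = b2, c2 = c2),
            sse = pr$sse)
      }
    lower <- c(a0 = -Inf, a1 = 0, b1 = -Inf, c1 = 1, a2 = 0, b2 = -Inf, c2 = 1)
    upper <- c(a0 = Inf, a1 = Inf, b1 = Inf, c1 = 360, a2 = Inf, b2 = Inf, c2 = 360)
  }
  if (!length(cand)) return(empty)
  ord <- order(vapply(cand, `[[`, numeric(1), "sse"))
  # polish from the best profile candidate; the grid separates the one- vs
  # two-bump basins, so a single Levenberg-Marquardt run suffices
  best <- NULL
  for (j in ord[1L]) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = cand[[j]]$par, fn = resid_fun,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss_res <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || ss_res < best$ss_res)
      best <- list(par = fit$par, ss_res = ss_res)
    if (best$ss_res / ss_tot < 1e-4) break  # essentially perfect fit
  }
  if (is.null(best)) return(empty)
  p <- best$par
  co <- c(a0 = unname(p["a0"]), a1 = unname(p["a1"]),
          b1 = wrap360(unname(p["b1"])), c1 = unname(p["c1"]),
          a2 = if (n_terms == 2L) unname(p["a2"]) else 0,
          b2 = if (n_terms == 2L) wrap360(unname(p["b2"])) else NA_real_,
          c2 = if (n_terms == 2L) unname(p["c2"]) else NA_real_)
  names(co) <- c("a0", "a1", "b1", "c1", "a2", "b2", "c2")
  # canonical ordering: term 1 carries the larger amplitude
  if (n_terms == 2L && co["a2"] > co["a1"]) {
    co[c("a1", "b1", "c1", "a2", "b2", "c2")] <-
      co[c("a2", "b2", "c2", "a1", "b1", "c1")]
  }
  fitted_full <- rep(NA_real_, length(y))
  fitted_full[ok] <- model(p)
  list(coef = co, r2 = 1 - best$ss_res / ss_tot, fitted = fitted_full,
       converged = TRUE)
}

#' Evaluate a sum-of-Gaussians curve from coefficients
#' @param coef named coefficients as returned by [fit_sum_of_gaussians()].
#' @param x angles in degrees.
#' @return curve values.
#' @export
eval_sum_of_gaussians <- function(coef, x = bin_centers_deg(60)) {
  y <- rep(coef[["a0"]], length(x))
  if (!is.na(coef[["b1"]]) && coef[["a1"]] > 0)
    y <- y + coef[["a1"]] * exp(-(circ_diff(x, coef[["b1"]]) / coef[["c1"]])^2)
  if (!is.na(coef[["b2"]]) && coef[["a2"]] > 0)
    y <- y + coef[["a2"]] * exp(-(circ_diff(x, coef[["b2"]]) / coef[["c2"]])^2)
  y
}
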