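#' Guinier fit of the low-angle region
#'
#' Fits `ln I(q) = ln I(0) - q^2 Rg^2 / 3` by error-weighted linear
#' regression of `ln I` on `q^2`.  The fitting window is found
#' iteratively: starting from the smallest admissible q, points are
#' included while `q * Rg_current <= qmax_rg_limit`, the fit repeated,
#' and the window updated until the included set is stable (at most 20
#' iterations).
#'
#' @param curve a [scatter_curve()].
#' @param qmax_rg_limit upper limit on `q * Rg` for points in the
#'   window (default 1.3, the conventional validity bound).
#' @param qmin optional explicit lower q cutoff, 1/Angstrom, for
#'   excluding beamstop-affected points; no automatic low-q rejection
#'   is performed.
#' @return An object of class `guinier_fit` with fields `rg`, `i0`,
#'   `q_range_used`, `n_points`, `fit_sd_rg`, `qmax_rg_product`, and a
#'   logical `degenerate` flag (slope >= 0, Rg reported as 0).
#' @export
guinier_fit <- function(curve, qmax_rg_limit = 1.3, qmin = NULL) {
  stopifnot(inherits(curve, "saxs_curve"))
  q <- curve$q
  I <- curve$intensity
  sig <- curve_sigma_or_unit(curve)
  adm <- if (is.null(qmin)) rep(TRUE, length(q)) else q >= qmin
  if (any(I[adm] <= 0))
    stop("negative or zero intensities in the admissible window")
  qa <- q[adm]; Ia <- I[adm]; sa <- sig[adm]
  if (length(qa) < 5) stop("fewer than 5 admissible points")

  fit_window <- function(k) {
    ## weighted regression of ln I on q^2 over the first k points;
    ## var(ln I) = (sigma / I)^2
    x <- qa[1:k]^2
    y <- log(Ia[1:k])
    w <- (Ia[1:k] / sa[1:k])^2
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    b <- fit$coefficients
    ## slope covariance for fit_sd_rg
    X <- cbind(1, x)
    XtWX <- crossprod(X * w, X)
    dof <- max(k - 2, 1)
    s2 <- sum(w * fit$residuals^2) / dof
    cov <- s2 * solve(XtWX)
    list(i0 = exp(b[1]), slope = b[2], sd_slope = sqrt(cov[2, 2]))
  }

  k <- min(5L, length(qa))
  prev_k <- -1L
  f <- fit_window(k)
  iter <- 0
  while (k != prev_k && iter < 20) {
    iter <- iter + 1
    prev_k <- k
    rg_cur <- if (f$slope < 0) sqrt(-3 * f$slope) else 0
    if (rg_cur > 0) {
      k <- max(5L, sum(qa * rg_cur <= qmax_rg_limit))
      k <- min(k, length(qa))
    }
    f <- fit_window(k)
  }
  if (k != prev_k) warning("Guinier window did not stabilize in 20 iterations")

  degenerate <- f$slope >= 0
  rg <- if (degenerate) 0 else sqrt(-3 * f$slope)
  sd_rg <- if (degenerate || rg == 0) NA_real_ else 3 * f$sd_slope / (2 * rg)
  structure(list(
    rg = unname(rg), i0 = unname(f$i0),
    q_range_used = c(qa[1], qa[k]), n_points = k,
    fit_sd_rg = unname(sd_rg),
    qmax_rg_product = unname(qa[k] * rg),
    degenerate = degenerate
  ), class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Guinier fit: degenerate (non-negative slope), Rg ~ 0\n")
  } else {
    cat(sprintf(
      "Guinier fit: Rg = %.2f +/- %.2f A, I(0) = %.4g (%d pts, q in [%.4g, %.4g], qmax*Rg = %.2f)\n",
      x$rg, x$fit_sd_rg, x$i0, x$n_points,
      x$q_range_used[1], x$q_range_used[2], x$qmax_rg_product))
  }
  invisible(x)
}

## Extend a curve to q = 0 using its Guinier fit: n_extra synthetic
## points on [0, qmin) with I = I0 exp(-q^2 Rg^2 / 3).  Returns plain
## vectors (q = 0 is admissible here) for use in invariant integrals.
guinier_extrapolate <- function(curve, gf = NULL, n_extra = 20) {
  if (is.null(gf)) gf <- guinier_fit(curve)
  if (gf$degenerate) stop("cannot extrapolate a degenerate Guinier fit")
  q_extra <- seq(0, curve$q[1], length.out = n_extra + 1)[1:n_extra]
  I_extra <- gf$i0 * exp(-q_extra^2 * gf$rg^2 / 3)
  list(q = c(q_extra, curve$q), intensity = c(I_extra, curve$intensity),
       guinier = gf)
}
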