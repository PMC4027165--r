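#' Per-frame Guinier Rg trace of a time series
#'
#' Runs [guinier_fit()] on every frame of a stopped-flow series and
#' condenses the results into a trace of (time, Rg, sd).  Frames whose
#' fit fails or degenerates are reported with the failure reason in the
#' returned table, never dropped silently.
#'
#' @param series a [time_series()].
#' @param guinier_limit `qmax_rg_limit` passed to [guinier_fit()].
#' @return A data frame with columns `time` (hours), `rg`, `sd`
#'   (Angstrom; `NA` on failure) and `status` (`"ok"` or the reason).
#' @export
series_rg <- function(series, guinier_limit = 1.3) {
  stopifnot(inherits(series, "saxs_series"))
  rows <- lapply(seq_along(series$times), function(i) {
    out <- tryCatch({
      gf <- guinier_fit(series$frames[[i]], qmax_rg_limit = guinier_limit)
      if (gf$degenerate)
        data.frame(time = series$times[i], rg = NA_real_, sd = NA_real_,
                   status = "degenerate Guinier fit")
      else
        data.frame(time = series$times[i], rg = gf$rg, sd = gf$fit_sd_rg,
                   status = "ok")
    }, error = function(e)
      data.frame(time = series$times[i], rg = NA_real_, sd = NA_real_,
                 status = conditionMessage(e)))
    out
  })
  tab <- do.call(rbind, rows)
  if (all(tab$status != "ok")) stop("Guinier fit failed on every frame")
  rownames(tab) <- NULL
  tab
}

#' Per-frame mixture fractions of a two-state series
#'
#' Decomposes every frame of a series as a non-negative mixture of two
#' end-member curves (via [fit_mixture()]) and returns the trace of the
#' large-species fraction over time, with the per-frame reduced
#' chi-square.
#'
#' @param series a [time_series()].
#' @param endmember_small,endmember_large [scatter_curve()]s of the
#'   pure small and large species, covering the frames' q range.
#' @return A data frame with columns `time` (hours), `fraction_large`,
#'   `chi2`.
#' @export
fractions_from_series <- function(series, endmember_small, endmember_large) {
  stopifnot(inherits(series, "saxs_series"))
  comps <- list(small = endmember_small, large = endmember_large)
  rows <- lapply(seq_along(series$times), function(i) {
    mf <- fit_mixture(series$frames[[i]], comps)
    data.frame(time = series$times[i],
               fraction_large = unname(mf$weights["large"]),
               chi2 = mf$chi2)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Fit a first-order conversion model to a fraction trace
#'
#' Models the decaying fraction of the larger species as driven by
#' single-exponential substrate consumption:
#' `f_large(t) = f0 * exp(-k t)`.  Fit by weighted least squares over
#' `(k, f0)` (Levenberg-Marquardt, started from the log-linear
#' estimate); deterministic.  The sub-second assembly step is treated
#' as instantaneous, so `f0` is the fraction at the dead time.
#'
#' @param observed data frame with columns `time` (hours) and
#'   `fraction_large` (in `[0, 1]`), optionally `sd` (per-point error;
#'   unit weights if absent).
#' @param model only `"first-order"` is implemented (enum kept for
#'   extension).
#' @return An object of class `kinetic_fit`: `k_hyd` (1/hour),
#'   `half_life` (hours), `f0`, `f_large` (predicted per input time),
#'   `residuals`, and `non_identifiable` flag.
#' @export
fit_conversion <- function(observed, model = "first-order") {
  model <- match.arg(model, "first-order")
  stopifnot(is.data.frame(observed),
            all(c("time", "fraction_large") %in% names(observed)))
  t <- observed$time
  f <- observed$fraction_large
  if (length(t) < 4) stop("need at least 4 time points")
  if (any(f < -1e-9) || any(f > 1 + 1e-9)) stop("fractions must lie in [0, 1]")
  w <- if ("sd" %in% names(observed)) 1 / observed$sd^2 else rep(1, length(t))

  if (stats::sd(f) < 1e-12 || all(f <= 0)) {
    return(structure(list(k_hyd = NA_real_, half_life = NA_real_,
                          f0 = mean(f), f_large = rep(mean(f), length(t)),
                          residuals = f - mean(f), non_identifiable = TRUE),
                     class = "kinetic_fit"))
  }

  ## log-linear start values (positive fractions only)
  pos <- f > 0
  sl <- stats::lm.wfit(cbind(1, t[pos]), log(f[pos]), w[pos])$coefficients
  k0 <- max(-sl[2], 1e-6)
  f0_0 <- min(max(exp(sl[1]), 1e-6), 1.5)

  fit <- minpack.lm::nlsLM(
    fraction_large ~ f0 * exp(-k * time),
    data = data.frame(time = t, fraction_large = f),
    start = list(f0 = f0_0, k = k0),
    weights = w,
    lower = c(f0 = 0, k = 0), upper = c(f0 = 1.5, k = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  k <- unname(cf["k"])
  if (!is.finite(k) || k <= 1e-8) {
    return(structure(list(k_hyd = NA_real_, half_life = NA_real_,
                          f0 = unname(cf["f0"]),
                          f_large = rep(unname(cf["f0"]), length(t)),
                          residuals = f - unname(cf["f0"]),
                          non_identifiable = TRUE),
                     class = "kinetic_fit"))
  }
  pred <- unname(cf["f0"]) * exp(-k * t)
  structure(list(k_hyd = k, half_life = log(2) / k, f0 = unname(cf["f0"]),
                 f_large = pred, residuals = f - pred,
                 non_identifiable = FALSE),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$non_identifiable) {
    cat("Kinetic fit: non-identifiable (flat fraction trace)\n")
  } else {
    cat(sprintf(
      "Kinetic fit: k = %.4g /h (half-life %.3g h), f0 = %.3f, RMS resid %.3g\n",
      x$k_hyd, x$half_life, x$f0, sqrt(mean(x$residuals^2))))
  }
  invisible(x)
}
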