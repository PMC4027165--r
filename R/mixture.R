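#' Fit a curve as a non-negative mixture of component curves
#'
#' Decomposes a target curve as `I(q) = s * sum_k w_k I_k(q)` with
#' `w_k >= 0`, `sum w_k = 1`, the conformer-population analysis used to
#' resolve coexisting open/closed states in solution.  Components are
#' resampled onto the target q grid by linear interpolation (target
#' points outside every component's range are dropped with a message);
#' the error-weighted non-negative least-squares problem over the raw
#' amplitudes `s * w_k` is solved exactly (Lawson-Hanson NNLS via
#' `pracma::lsqnonneg`) and the amplitudes normalized.
#'
#' Weights are intensity-share fractions of the fitted combination.
#' For equal-mass conformers (the open/closed case) these coincide with
#' volume fractions; for components of unequal forward scattering a
#' warning notes that the fractions are intensity-weighted.
#'
#' @param target a [scatter_curve()] to decompose.
#' @param components list of at least 2 [scatter_curve()] components.
#' @param allow_constant add a free additive constant background
#'   (default `FALSE`).
#' @return An object of class `mixture_fit`: `weights` (named by
#'   component labels), `scale`, `chi2` (reduced), `constant` (0 unless
#'   enabled), `component_labels`, `degenerate` (collinearity flag),
#'   `n_used` (target points retained).
#' @export
fit_mixture <- function(target, components, allow_constant = FALSE) {
  stopifnot(inherits(target, "saxs_curve"))
  if (!is.list(components) || length(components) < 2)
    stop("need at least 2 components")
  lapply(components, function(x) stopifnot(inherits(x, "saxs_curve")))
  K <- length(components)
  labels <- names(components)
  if (is.null(labels)) labels <- rep("", K)
  labels <- vapply(seq_len(K), function(k) {
    if (nzchar(labels[k])) return(labels[k])
    lb <- components[[k]]$label
    if (nzchar(lb)) lb else paste0("component_", k)
  }, character(1))
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")

  M <- vapply(components, interp_intensity, numeric(length(target$q)),
              q_new = target$q)
  keep <- rowSums(is.na(M)) == 0
  if (!any(keep)) stop("empty overlap of q ranges")
  if (sum(!keep) > 0)
    message("fit_mixture: dropped ", sum(!keep),
            " target point(s) outside the component q ranges")
  q <- target$q[keep]
  I <- target$intensity[keep]
  sig <- curve_sigma_or_unit(target)[keep]
  M <- M[keep, , drop = FALSE]

  A <- M / sig
  if (allow_constant) {
    ## signed constant as a +/- column pair so NNLS stays applicable
    A <- cbind(A, 1 / sig, -1 / sig)
  }
  b <- I / sig

  cond_num <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
  degenerate <- !is.finite(cond_num) || cond_num > 1e10
  if (degenerate)
    warning("components are (near-)collinear; weights are degenerate")

  x <- pracma::lsqnonneg(A, b)$x
  amp <- x[seq_len(K)]
  const <- if (allow_constant) x[K + 1] - x[K + 2] else 0
  s <- sum(amp)
  if (s <= 0) {
    warning("all component amplitudes fitted to zero")
    w <- rep(0, K)
  } else {
    w <- amp / s
  }

  i0_comp <- vapply(components, function(cc) cc$intensity[1], numeric(1))
  if (s > 0 && diff(range(i0_comp)) / max(i0_comp) > 0.2)
    warning("components differ in forward scattering; ",
            "fractions are intensity-weighted, not mass fractions")

  fitI <- as.numeric(M %*% amp) + const
  dof <- max(length(q) - (K + as.integer(allow_constant)), 1)
  chi2 <- sum(((I - fitI) / sig)^2) / dof

  structure(list(weights = stats::setNames(w, labels), scale = s,
                 chi2 = chi2, constant = const,
                 component_labels = labels, degenerate = degenerate,
                 n_used = length(q)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Mixture fit (", x$n_used, " points, reduced chi2 = ",
      format(x$chi2, digits = 4), ")\n", sep = "")
  for (k in seq_along(x$weights))
    cat(sprintf("  %-24s %6.2f %%\n", x$component_labels[k],
                100 * x$weights[k]))
  if (x$degenerate) cat("  [degenerate: components nearly collinear]\n")
  invisible(x)
}

#' Apparent radius of gyration of a mixture
#'
#' In the Guinier regime a mixture of species scatters with an apparent
#' `Rg_app^2 = sum(w_i I0_i Rg_i^2) / sum(w_i I0_i)`: each component
#' contributes its squared Rg weighted by its share of the forward
#' scattering.  Used to interpret Guinier traces of time-resolved
#' two-state series.
#'
#' @param weights non-negative fractions, summing to 1.
#' @param component_rgs per-component Rg, Angstrom.
#' @param component_i0s per-component forward scattering I(0).
#' @return Apparent Rg in Angstrom.
#' @export
apparent_rg_of_mixture <- function(weights, component_rgs, component_i0s) {
  stopifnot(length(weights) == length(component_rgs),
            length(weights) == length(component_i0s))
  if (any(weights < 0) || any(component_rgs <= 0) || any(component_i0s <= 0))
    stop("inputs must be positive (weights non-negative)")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  sqrt(sum(weights * component_i0s * component_rgs^2) /
         sum(weights * component_i0s))
}
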