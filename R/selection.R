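#' Score a model curve against an experimental curve
#'
#' Computes the reduced chi-square of an optimally scaled model,
#' `chi2 = 1/(N - m) * sum[(I_e - c I_m - b)^2 / sigma^2]`, with the
#' scale `c` (and constant `b`, if enabled) from the closed-form
#' weighted least-squares solution, plus an R-factor
#' `R_sas = sum|I_e - c I_m - b| / sum|I_e|` on the fitted curve.  The
#' model curve is interpolated onto the experimental q grid; `m` is 1
#' (scale) or 2 (scale + constant).
#'
#' @param exp_curve experimental [scatter_curve()].
#' @param model_curve model [scatter_curve()]; must cover the
#'   experimental q range (at least in part).
#' @param fit_constant also fit an additive constant (default `FALSE`).
#' @return An object of class `fit_score`: `chi2`, `r_sas`, `scale`,
#'   `constant`, `n_used`.
#' @export
score_model <- function(exp_curve, model_curve, fit_constant = FALSE) {
  stopifnot(inherits(exp_curve, "saxs_curve"),
            inherits(model_curve, "saxs_curve"))
  Im <- interp_intensity(model_curve, exp_curve$q)
  keep <- !is.na(Im)
  if (!any(keep)) stop("no q overlap between experiment and model")
  Ie <- exp_curve$intensity[keep]
  Im <- Im[keep]
  sig <- curve_sigma_or_unit(exp_curve)[keep]
  if (all(Im == 0)) stop("all-zero model curve")
  w <- 1 / sig^2
  if (fit_constant) {
    X <- cbind(Im, 1)
    beta <- solve(crossprod(X * w, X), crossprod(X * w, Ie))
    cc <- beta[1]; b <- beta[2]
  } else {
    cc <- sum(w * Ie * Im) / sum(w * Im^2)
    b <- 0
  }
  res <- Ie - cc * Im - b
  m <- 1 + as.integer(fit_constant)
  structure(list(
    chi2 = sum(w * res^2) / max(length(Ie) - m, 1),
    r_sas = sum(abs(res)) / sum(abs(Ie)),
    scale = unname(cc), constant = unname(b), n_used = length(Ie)
  ), class = "fit_score")
}

#' @export
print.fit_score <- function(x, ...) {
  cat(sprintf("fit score: chi2 = %.4g, R_sas = %.4g, scale = %.4g (n = %d)\n",
              x$chi2, x$r_sas, x$scale, x$n_used))
  invisible(x)
}

#' Rank candidate poses against an experimental curve
#'
#' For each candidate model: compute its Rg; exclude (and log) poses
#' whose Rg differs from the experimental Guinier Rg by more than
#' `rg_window`; compute the Debye curve of each survivor on the
#' experimental q grid and score it with [score_model()].  Survivors
#' are ordered by increasing chi2, ties broken by R-factor then label,
#' so the ranking is deterministic and stable under permutation of the
#' input list.
#'
#' @param exp_curve experimental [scatter_curve()].
#' @param models list of [coordinate_set()] candidates (named, or
#'   labelled via their `label` fields).
#' @param rg_window Rg prefilter half-width, Angstrom (default 5).
#' @param ff a [ff_config()] for the forward model.
#' @param fit_constant passed to [score_model()].
#' @return An object of class `pose_ranking`: `table` (data frame with
#'   label, chi2, r_sas, scale, rg_model, rg_delta, rank), `rg_exp`,
#'   and `filter_log` (data frame of excluded poses and reasons).
#' @export
rank_poses <- function(exp_curve, models, rg_window = 5, ff = ff_config(),
                       fit_constant = FALSE) {
  stopifnot(inherits(exp_curve, "saxs_curve"))
  if (!is.list(models) || length(models) < 2)
    stop("need at least 2 candidate models")
  labels <- names(models)
  if (is.null(labels)) labels <- rep("", length(models))
  auto <- !nzchar(labels)
  labels[auto] <- vapply(which(auto), function(i) {
    lb <- models[[i]]$label
    if (nzchar(lb)) lb else sprintf("model_%03d", i)
  }, character(1))
  labels <- make.unique(labels, sep = "_")

  gf <- guinier_fit(exp_curve)
  rg_exp <- gf$rg
  rg_mod <- vapply(models, rg_of_coords, numeric(1))
  delta <- rg_mod - rg_exp
  excluded <- abs(delta) > rg_window
  filter_log <- data.frame(
    label = labels[excluded],
    rg_model = rg_mod[excluded],
    rg_delta = delta[excluded],
    reason = sprintf("|Rg_model - Rg_exp| = %.2f A > window %.2f A",
                     abs(delta[excluded]), rg_window),
    stringsAsFactors = FALSE)
  if (all(excluded)) {
    err <- simpleError("all poses excluded by the Rg prefilter")
    err$filter_log <- filter_log
    stop(err)
  }

  surv <- which(!excluded)
  scores <- lapply(surv, function(i) {
    mc <- debye_curve(models[[i]], exp_curve$q, ff = ff)
    score_model(exp_curve, mc, fit_constant = fit_constant)
  })
  tab <- data.frame(
    label = labels[surv],
    chi2 = vapply(scores, `[[`, numeric(1), "chi2"),
    r_sas = vapply(scores, `[[`, numeric(1), "r_sas"),
    scale = vapply(scores, `[[`, numeric(1), "scale"),
    rg_model = rg_mod[surv],
    rg_delta = delta[surv],
    stringsAsFactors = FALSE)
  ord <- order(tab$chi2, tab$r_sas, tab$label)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, rg_exp = rg_exp, filter_log = filter_log),
            class = "pose_ranking")
}

#' @export
print.pose_ranking <- function(x, ...) {
  cat(sprintf("Pose ranking vs Rg_exp = %.2f A (%d scored, %d excluded)\n",
              x$rg_exp, nrow(x$table), nrow(x$filter_log)))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Discriminate assembly stoichiometries against a curve
#'
#' Scores each labelled candidate assembly (Debye curve, optimal scale,
#' reduced chi2) against the experimental curve and reports the margin
#' `chi2_secondbest / chi2_best`.  The call declares the stoichiometry
#' "discriminated" when the margin reaches `margin_threshold` (default
#' 3): below that, the data cannot distinguish the hypotheses.
#'
#' @param exp_curve experimental [scatter_curve()].
#' @param candidates named list of [coordinate_set()] assembly models.
#' @param ff a [ff_config()].
#' @param margin_threshold chi2 ratio declaring discrimination.
#' @return An object of class `stoichiometry_report`: `table` (label,
#'   chi2, r_sas, rg_model, rank), `winner`, `margin`, `discriminated`.
#' @export
discriminate_stoichiometry <- function(exp_curve, candidates,
                                       ff = ff_config(),
                                       margin_threshold = 3) {
  if (!is.list(candidates) || length(candidates) < 2)
    stop("need at least 2 labelled candidates")
  labels <- names(candidates)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("candidates must be a named list")
  scores <- lapply(candidates, function(m) {
    mc <- debye_curve(m, exp_curve$q, ff = ff)
    score_model(exp_curve, mc)
  })
  tab <- data.frame(
    label = labels,
    chi2 = vapply(scores, `[[`, numeric(1), "chi2"),
    r_sas = vapply(scores, `[[`, numeric(1), "r_sas"),
    rg_model = vapply(candidates, rg_of_coords, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$chi2, tab$r_sas, tab$label)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  margin <- if (tab$chi2[1] == 0) Inf else tab$chi2[2] / tab$chi2[1]
  structure(list(table = tab, winner = tab$label[1], margin = margin,
                 discriminated = margin >= margin_threshold),
            class = "stoichiometry_report")
}

#' @export
print.stoichiometry_report <- function(x, ...) {
  cat(sprintf("Stoichiometry discrimination: winner '%s', margin %.3g (%s)\n",
              x$winner, x$margin,
              if (x$discriminated) "discriminated" else "not discriminated"))
  print(x$table)
  invisible(x)
}
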