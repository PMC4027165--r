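#' Candidate bead lattice for shape reconstruction
#'
#' Builds the deterministic candidate-position set the annealer selects
#' from: beads of radius `bead_radius` packed (hexagonal-close-packed
#' or simple cubic, spacing `2 * bead_radius`) into a search sphere of
#' diameter `search_dmax`.  Neighbor lists connect beads within 1.1x
#' the lattice spacing.
#'
#' @param search_dmax diameter of the search sphere, Angstrom; must
#'   exceed `4 * bead_radius`.
#' @param bead_radius bead radius, Angstrom.
#' @param packing `"hcp"` (default; ~0.74 packing density) or
#'   `"cubic"` (~0.52).
#' @return An object of class `bead_lattice`: `positions`, `bead_radius`,
#'   `spacing`, `packing`, `neighbors` (list of integer vectors),
#'   `search_dmax`.
#' @export
make_lattice <- function(search_dmax, bead_radius,
                         packing = c("hcp", "cubic")) {
  packing <- match.arg(packing)
  if (!is.finite(search_dmax) || !is.finite(bead_radius) ||
      bead_radius <= 0 || search_dmax <= 4 * bead_radius)
    stop("degenerate geometry: need search_dmax > 4 * bead_radius")
  a <- 2 * bead_radius
  R <- search_dmax / 2
  if (packing == "cubic") {
    g <- seq(-floor(R / a) * a, floor(R / a) * a, by = a)
    p <- as.matrix(expand.grid(x = g, y = g, z = g))
  } else {
    ## ABAB close packing: in-plane hexagonal rows, alternating layers
    ni <- ceiling(R / a) + 1
    nk <- ceiling(R / (a * sqrt(6) / 3)) + 1
    idx <- expand.grid(i = -ni:ni, j = -ni:ni, k = -nk:nk)
    p <- cbind(
      x = a * (idx$i + ((idx$j + idx$k) %% 2) / 2),
      y = a * sqrt(3) / 2 * (idx$j + (idx$k %% 2) / 3),
      z = a * sqrt(6) / 3 * idx$k)
  }
  p <- p[rowSums(p^2) <= R^2, , drop = FALSE]
  if (nrow(p) < 8) stop("degenerate geometry: too few candidate sites")
  d <- as.matrix(stats::dist(p))
  nb <- apply(d <= 1.1 * a & d > 0, 1, which, simplify = FALSE)
  structure(list(positions = p, bead_radius = bead_radius, spacing = a,
                 packing = packing, neighbors = nb,
                 search_dmax = search_dmax),
            class = "bead_lattice")
}

#' @export
print.bead_lattice <- function(x, ...) {
  cat(sprintf("bead_lattice: %d %s sites, bead radius %g A, search sphere %g A\n",
              nrow(x$positions), x$packing, x$bead_radius, x$search_dmax))
  invisible(x)
}

## Largest connected component fraction of the occupied subgraph.
largest_cc_fraction <- function(occ_idx, neighbors) {
  n <- length(occ_idx)
  if (n == 0) return(0)
  npos <- max(vapply(neighbors, function(x) if (length(x)) max(x) else 0L,
                     numeric(1)), occ_idx)
  pos <- integer(npos)
  pos[occ_idx] <- seq_len(n)
  seen <- logical(n)
  stack <- integer(n)
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    top <- 1L; stack[1] <- s; seen[s] <- TRUE; size <- 0L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L; size <- size + 1L
      nb <- pos[neighbors[[occ_idx[v]]]]
      nb <- nb[nb > 0L]
      nb <- nb[!seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        stack[(top + 1L):(top + length(nb))] <- nb
        top <- top + length(nb)
      }
    }
    if (size > best) best <- size
    if (best > n %/% 2L) break
  }
  best / n
}

#' Ab initio bead-model reconstruction by simulated annealing
#'
#' Searches for an occupancy pattern on a [make_lattice()] whose
#' uniform-bead Debye curve fits the data, under penalties for loose
#' beads (occupied beads with fewer than 3 occupied neighbors) and for
#' disconnected fragments.  Metropolis single-bead flips with a
#' geometric temperature schedule; the initial state is a compact
#' central blob whose Rg matches the curve's Guinier Rg.  The search is
#' fully reproducible given `seed`.
#'
#' The objective is `chi2 + w_loose * loose + w_disc * disconnect`,
#' where chi2 uses the curve's errors (or 1 percent of I(q) when the
#' curve carries none), `loose` is the loose-bead fraction, and
#' `disconnect = 1 - largest component fraction` (recomputed once per
#' temperature step).  Scattering updates are incremental through a
#' pair-distance histogram.  The best-visited state is returned; if its
#' largest connected component holds less than 95 percent of the beads
#' the model is flagged `disconnected` rather than silently accepted.
#'
#' @param curve target [scatter_curve()]; must support a Guinier fit.
#' @param lattice a [make_lattice()].
#' @param schedule list with `t0` (initial temperature; `NULL` scales
#'   to a tenth of the initial objective), `cooling` (geometric factor),
#'   `steps_per_t` (`NULL` = one sweep of the candidate count), and
#'   `t_min_frac` (stop when T drops below this fraction of t0).
#' @param penalties numeric: `loose` and `disconnect` weights.
#' @param seed integer seed.
#' @param n_q number of q points the objective is evaluated on
#'   (subsampled from the curve for speed).
#' @return An object of class `shape_model`: `occupancy` (indices into
#'   the lattice), `model` (a [coordinate_set()] of occupied beads),
#'   `final_score`, `chi2`, `rg`, `anneal_log` (per-temperature data
#'   frame), `disconnected`, `seed`, `lattice`.
#' @export
anneal_shape <- function(curve, lattice,
                         schedule = list(t0 = NULL, cooling = 0.85,
                                         steps_per_t = NULL,
                                         t_min_frac = 1e-4),
                         penalties = c(loose = 1, disconnect = 5),
                         seed = 1, n_q = 80) {
  stopifnot(inherits(curve, "saxs_curve"), inherits(lattice, "bead_lattice"))
  gf <- guinier_fit(curve)
  if (gf$degenerate) stop("curve has no usable Guinier region")
  P <- lattice$positions
  ncand <- nrow(P)
  nbs <- lattice$neighbors

  ## objective grid: subsample the curve
  pick <- unique(round(seq(1, length(curve$q), length.out = min(n_q, length(curve$q)))))
  q <- curve$q[pick]
  Ie <- curve$intensity[pick]
  sig <- if (is.null(curve$sigma)) 0.01 * abs(Ie) else curve$sigma[pick]
  ## floor the objective errors at 0.1% of the peak: near form-factor
  ## minima the bead discretization error dominates any realistic sigma,
  ## and unfloored weights would make the minima rule the whole fit
  sig <- pmax(sig, 1e-3 * max(abs(Ie)))
  wgt <- 1 / sig^2
  fa2 <- sphere_amplitude(q, lattice$bead_radius)^2

  ## pair-distance bins: 0.05 A width keeps the binning phase error
  ## below 0.01 rad over the SAXS q range, i.e. effectively exact
  bw <- 0.05
  D <- as.matrix(stats::dist(P))
  B <- matrix(as.integer(round(D / bw)), ncand, ncand)  # 0 = self
  nbin <- max(B)
  rbin <- seq_len(nbin) * bw
  S <- sinc(outer(q, rbin))                 # n_q x nbin

  chi2_of <- function(I_model) {
    cc <- sum(wgt * Ie * I_model) / sum(wgt * I_model^2)
    sum(wgt * (Ie - cc * I_model)^2) / max(length(q) - 1, 1)
  }

  with_seed(seed, {
    ## initial blob: central sites within the sphere radius matching Rg
    r0 <- gf$rg * sqrt(5 / 3)
    occ <- rowSums(P^2) <= r0^2
    if (sum(occ) < 8) occ <- rank(rowSums(P^2), ties.method = "first") <= 8

    hist_cnt <- integer(nbin)
    oi <- which(occ)
    if (length(oi) > 1) {
      bb <- B[oi, oi][upper.tri(diag(length(oi)))]
      hist_cnt <- tabulate(bb, nbin)
    }
    n_occ <- sum(occ)
    I_mod <- fa2 * (n_occ + 2 * as.numeric(S %*% hist_cnt))
    nb_cnt <- vapply(seq_len(ncand), function(i) sum(occ[nbs[[i]]]), integer(1))

    loose_frac <- function() {
      oi <- which(occ)
      if (!length(oi)) return(1)
      mean(nb_cnt[oi] < 3)
    }
    disc <- 1 - largest_cc_fraction(which(occ), nbs)
    chi2 <- chi2_of(I_mod)
    obj <- chi2 + penalties[["loose"]] * loose_frac() +
      penalties[["disconnect"]] * disc

    t0 <- schedule$t0
    if (is.null(t0)) t0 <- obj / 10
    steps <- schedule$steps_per_t
    if (is.null(steps)) steps <- ncand
    cooling <- schedule$cooling
    t_min <- t0 * schedule$t_min_frac

    best <- list(occ = occ, obj = obj, chi2 = chi2)
    log_rows <- list()
    Tcur <- t0
    while (Tcur >= t_min) {
      acc <- 0L
      rand_u <- stats::runif(steps)
      for (s in seq_len(steps)) {
        ## propose flips on the cluster surface only: occupied beads or
        ## empty sites adjacent to the cluster
        movable <- which(occ | nb_cnt > 0L)
        i <- movable[sample.int(length(movable), 1L)]
        turning_on <- !occ[i]
        if (!turning_on && n_occ <= 8) next
        oi <- which(occ); oi <- oi[oi != i]
        db <- tabulate(B[i, oi], nbin)
        sgn <- if (turning_on) 1 else -1
        I_new <- I_mod + fa2 * sgn * (1 + 2 * as.numeric(S %*% db))
        ## provisional state update for penalty terms
        occ[i] <- turning_on
        nb_cnt[nbs[[i]]] <- nb_cnt[nbs[[i]]] + sgn
        n_occ <- n_occ + sgn
        chi2_new <- chi2_of(I_new)
        obj_new <- chi2_new + penalties[["loose"]] * loose_frac() +
          penalties[["disconnect"]] * disc
        if (obj_new <= obj || rand_u[s] < exp(-(obj_new - obj) / Tcur)) {
          acc <- acc + 1L
          obj <- obj_new; chi2 <- chi2_new
          I_mod <- I_new
          hist_cnt <- hist_cnt + sgn * db
          if (obj < best$obj) best <- list(occ = occ, obj = obj, chi2 = chi2)
        } else {
          occ[i] <- !turning_on
          nb_cnt[nbs[[i]]] <- nb_cnt[nbs[[i]]] - sgn
          n_occ <- n_occ - sgn
        }
      }
      disc <- 1 - largest_cc_fraction(which(occ), nbs)
      obj <- chi2 + penalties[["loose"]] * loose_frac() +
        penalties[["disconnect"]] * disc
      log_rows[[length(log_rows) + 1]] <-
        data.frame(temperature = Tcur, acceptance = acc / steps,
                   chi2 = chi2, objective = obj, n_occ = n_occ)
      if (acc / steps < 0.01) break
      Tcur <- Tcur * cooling
    }

    occ_idx <- which(best$occ)
    cc_frac <- largest_cc_fraction(occ_idx, nbs)
    model <- coordinate_set(P[occ_idx, , drop = FALSE], weights = 1,
                            label = sprintf("anneal seed=%d", seed))
    structure(list(
      occupancy = occ_idx, model = model,
      final_score = best$obj, chi2 = best$chi2,
      rg = rg_of_coords(model),
      anneal_log = do.call(rbind, log_rows),
      disconnected = cc_frac < 0.95,
      largest_cc_fraction = cc_frac,
      seed = seed, lattice = lattice
    ), class = "shape_model")
  })
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "shape_model: %d beads, Rg %.2f A, chi2 %.4g, score %.4g%s (seed %d)\n",
    length(x$occupancy), x$rg, x$chi2, x$final_score,
    if (x$disconnected) " [DISCONNECTED]" else "", x$seed))
  invisible(x)
}

## --- superposition helpers -------------------------------------------

## Principal-axes frame of a weighted point set: centered coordinates
## rotated so the covariance eigenvectors align with x >= y >= z.
principal_frame <- function(pos, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(pos))
  ctr <- colSums(pos * w) / sum(w)
  X <- sweep(pos, 2, ctr)
  C <- crossprod(X * w, X) / sum(w)
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(coords = X %*% V, values = e$values)
}

## The four proper-rotation axis-sign conventions.
.sign_flips <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))

## Mean nearest-neighbor distance from each row of a to rows of b.
mean_nn_dist <- function(a, b) {
  ## chunked to bound memory on large bead sets
  n <- nrow(a)
  out <- numeric(n)
  step <- max(1, floor(2e6 / nrow(b)))
  for (s in seq(1, n, by = step)) {
    idx <- s:min(s + step - 1, n)
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[idx, , drop = FALSE] %*% t(b)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  mean(out)
}

## Mean spacing of a point set: average nearest-neighbor distance.
mean_nn_spacing <- function(a) {
  d <- as.matrix(stats::dist(a))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Shape-agreement score between two bead/point models
#'
#' A normalized-spatial-discrepancy-style metric: both models are
#' centered and rotated into their principal-axes frames, the best of
#' the four proper axis-sign conventions is taken, and the symmetric
#' mean nearest-neighbor distance between the sets is divided by the
#' mean nearest-neighbor spacing of the sets themselves.  0 for
#' identical sets (invariant under rigid motion); values up to ~1
#' indicate similar shapes; clearly dissimilar shapes score above 1.
#'
#' @param a,b [coordinate_set()]s.
#' @return Dimensionless non-negative score.
#' @export
shape_agreement <- function(a, b) {
  stopifnot(inherits(a, "coord_set"), inherits(b, "coord_set"))
  fa <- principal_frame(a$positions, a$weights)
  fb <- principal_frame(b$positions, b$weights)
  spacing <- (mean_nn_spacing(fa$coords) + mean_nn_spacing(fb$coords)) / 2
  best <- Inf
  for (k in seq_len(nrow(.sign_flips))) {
    bc <- sweep(fb$coords, 2, .sign_flips[k, ], `*`)
    d <- (mean_nn_dist(fa$coords, bc) + mean_nn_dist(bc, fa$coords)) / 2
    best <- min(best, d)
  }
  best / spacing
}

#' Consensus of multiple annealing runs
#'
#' Aligns every reconstruction to the first by principal axes and
#' centroid (best of the four axis-sign conventions by nearest-neighbor
#' distance; centroid-only when the inertia tensor is near-degenerate,
#' i.e. for near-spherical models), snaps aligned beads to the nearest
#' lattice site, and votes per site: sites occupied in at least
#' `threshold` of the runs form the consensus model.
#'
#' @param models list of at least 2 [anneal_shape()] results from the
#'   same lattice family.
#' @param lattice the [make_lattice()] the runs used.
#' @param threshold minimum occupancy frequency (default 0.5;
#'   `threshold = 1` keeps the intersection of all runs).
#' @return An object of class `shape_model` (no anneal log); the
#'   per-site occupancy frequency map is in `$frequency`.
#' @export
average_runs <- function(models, lattice, threshold = 0.5) {
  if (!is.list(models) || length(models) < 2)
    stop("need at least 2 models to average")
  lapply(models, function(m) stopifnot(inherits(m, "shape_model")))
  P <- lattice$positions
  ref_pos <- P[models[[1]]$occupancy, , drop = FALSE]
  ctr_ref <- colMeans(ref_pos)
  X_ref <- sweep(ref_pos, 2, ctr_ref)
  C_ref <- crossprod(X_ref) / nrow(X_ref)
  e_ref <- eigen(C_ref, symmetric = TRUE)
  V_ref <- e_ref$vectors
  if (det(V_ref) < 0) V_ref[, 3] <- -V_ref[, 3]
  degenerate_axes <- function(v) {
    (v[1] - v[2]) / v[1] < 0.05 || (v[2] - v[3]) / max(v[2], 1e-12) < 0.05
  }
  votes <- numeric(nrow(P))
  for (m in models) {
    pos <- P[m$occupancy, , drop = FALSE]
    ctr_m <- colMeans(pos)
    X_m <- sweep(pos, 2, ctr_m)
    fm <- principal_frame(pos)
    if (degenerate_axes(fm$values) || degenerate_axes(e_ref$values)) {
      aligned <- X_m              # centroid-only fallback
    } else {
      V_m <- eigen(crossprod(X_m) / nrow(X_m), symmetric = TRUE)$vectors
      if (det(V_m) < 0) V_m[, 3] <- -V_m[, 3]
      best <- NULL; bestd <- Inf
      for (k in seq_len(nrow(.sign_flips))) {
        ## rotate m's principal frame onto the reference's lattice frame
        cand <- X_m %*% V_m %*% diag(.sign_flips[k, ]) %*% t(V_ref)
        d <- mean_nn_dist(X_ref, cand)
        if (d < bestd) { bestd <- d; best <- cand }
      }
      aligned <- best
    }
    shifted <- sweep(aligned, 2, -ctr_ref)   # back to lattice coordinates
    d2 <- outer(rowSums(shifted^2), rowSums(P^2), "+") - 2 * shifted %*% t(P)
    nearest <- apply(d2, 1, which.min)
    votes[unique(nearest)] <- votes[unique(nearest)] + 1
  }
  freq <- votes / length(models)
  keep <- which(freq >= threshold)
  if (!length(keep)) stop("no lattice site reaches the occupancy threshold")
  model <- coordinate_set(P[keep, , drop = FALSE], weights = 1,
                          label = sprintf("consensus of %d runs", length(models)))
  structure(list(
    occupancy = keep, model = model, final_score = NA_real_,
    chi2 = NA_real_, rg = rg_of_coords(model), anneal_log = NULL,
    disconnected = largest_cc_fraction(keep, lattice$neighbors) < 0.95,
    largest_cc_fraction = largest_cc_fraction(keep, lattice$neighbors),
    seed = NA_integer_, lattice = lattice, frequency = freq
  ), class = "shape_model")
}
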