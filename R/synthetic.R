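## --- seeded generation utilities -------------------------------------

## Evaluate expr under a temporary RNG state seeded with `seed`;
## restores the caller's RNG state afterwards, so every generator is a
## pure function of (spec, seed) with no global side effects.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default momentum-transfer grid
#'
#' 400 linear points on `[0.01, 0.35]` 1/Angstrom, typical of modern
#' bio-SAXS beamline reductions.
#'
#' @param n number of points.
#' @param qmin,qmax grid limits, 1/Angstrom.
#' @return Numeric vector.
#' @export
default_q_grid <- function(n = 400, qmin = 0.01, qmax = 0.35) {
  seq(qmin, qmax, length.out = n)
}

#' Deterministic bead filling of a sphere
#'
#' Fills a sphere of the given radius with a cubic grid of beads,
#' weighting boundary beads by the fraction of their grid cell inside
#' the sphere (estimated on a `sub^3` subgrid).  Deterministic, no RNG.
#' Used as the uniform-density reference body for Debye-oracle checks
#' and shape-agreement ground truths.
#'
#' @param radius sphere radius, Angstrom.
#' @param spacing grid spacing, Angstrom.
#' @param sub cell-occupancy subsampling factor.
#' @param center sphere center (length-3).
#' @return A [coordinate_set()] with fractional boundary weights.
#' @export
bead_fill_sphere <- function(radius, spacing, sub = 4, center = c(0, 0, 0)) {
  stopifnot(radius > 0, spacing > 0, spacing < radius)
  g <- seq(-radius + spacing / 2, radius, by = spacing)
  p <- as.matrix(expand.grid(x = g, y = g, z = g))
  p <- p[rowSums(p^2) <= (radius + spacing)^2, , drop = FALSE]
  o <- (seq_len(sub) - 0.5) / sub - 0.5
  off <- as.matrix(expand.grid(o, o, o)) * spacing
  frac <- numeric(nrow(p))
  for (k in seq_len(nrow(off))) {
    s <- sweep(p, 2, -off[k, ])
    frac <- frac + (rowSums(s^2) <= radius^2)
  }
  frac <- frac / nrow(off)
  keep <- frac > 0
  coordinate_set(sweep(p[keep, , drop = FALSE], 2, -center),
                 weights = frac[keep],
                 label = sprintf("bead sphere R=%g", radius))
}

## --- toy assembly geometry -------------------------------------------

## Rotation matrix about the z axis (degrees).
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

## A "body" is a data frame of sphere lobes: center (cx, cy, cz),
## radius r, and subunit id (used by decoy generation).  The geometry
## constants below are tuned once so the generated toys land in the Rg
## regimes of the studied species (open/closed ~38/37 A, 1:1 complex
## ~52 A, extended 2:1 complex ~67 A); they are not protein-realistic.
lobes_alpha <- function(state = c("open", "closed")) {
  state <- match.arg(state)
  g <- if (state == "open") c(21.9, 46.7) else c(14, 44.76)
  data.frame(
    cx = c(-29.1, 29.1, -g[1], g[1]),
    cy = c(0, 0, g[2], g[2]),
    cz = 0,
    r = c(24.8, 24.8, 17.5, 17.5))
}

lobes_beta <- function() {
  data.frame(
    cx = c(-31.2, 31.2, -52, 52),
    cy = 0, cz = 0,
    r = c(26, 26, 18.2, 18.2))
}

transform_lobes <- function(lb, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(lb[, c("cx", "cy", "cz")]) %*% t(rot)
  lb$cx <- xyz[, 1] + shift[1]
  lb$cy <- xyz[, 2] + shift[2]
  lb$cz <- xyz[, 3] + shift[3]
  lb
}

## Lobe tables per species, with subunit ids (1 = mobile docked unit).
species_lobes <- function(species) {
  al_cl <- lobes_alpha("closed")
  be <- lobes_beta()
  switch(species,
    "open-dimer" = cbind(lobes_alpha("open"), subunit = 0),
    "closed-dimer" = cbind(al_cl, subunit = 0),
    "L-complex" = rbind(
      cbind(be, subunit = 0),
      cbind(transform_lobes(al_cl, rot_z(90), c(-39.1, -45.1, 0)), subunit = 1)),
    "extended-3-lobe" = rbind(
      cbind(be, subunit = 0),
      cbind(transform_lobes(al_cl, rot_z(90), c(-57.3, 0, 0)), subunit = 1),
      cbind(transform_lobes(al_cl, rot_z(-90), c(57.3, 0, 0)), subunit = 2)),
    "inverted-1:2" = rbind(
      cbind(al_cl, subunit = 0),
      cbind(transform_lobes(be, rot_z(90), c(-49, 0, 0)), subunit = 1),
      cbind(transform_lobes(be, rot_z(90), c(49, 0, 0)), subunit = 2)),
    "trna-L" = {
      arm1 <- data.frame(cx = seq(0, 48.8, by = 6.1), cy = 0, cz = 0, r = 9.5)
      arm2 <- data.frame(cx = 0, cy = seq(6.1, 43.8, by = 6.1), cz = 0, r = 9.5)
      cbind(rbind(arm1, arm2), subunit = 0)
    },
    stop("unknown species: ", species))
}

#' Specification of a synthetic toy assembly
#'
#' @param species one of `"open-dimer"`, `"closed-dimer"`,
#'   `"L-complex"` (an asymmetric 1:1 dimer-of-dimers),
#'   `"extended-3-lobe"` (a linear 2:1 A-B-A complex),
#'   `"inverted-1:2"` (the B-A-B control), `"trna-L"` (two
#'   perpendicular arms).
#' @param size_scale global size multiplier (1 = the tuned defaults).
#' @param seed integer seed controlling bead sampling.
#' @param n_beads approximate total bead count.
#' @return An object of class `toy_spec`.
#' @export
toy_spec <- function(species = c("open-dimer", "closed-dimer", "L-complex",
                                 "extended-3-lobe", "inverted-1:2", "trna-L"),
                     size_scale = 1, seed = 1, n_beads = 800) {
  species <- match.arg(species)
  if (!is.finite(size_scale) || size_scale <= 0)
    stop("size_scale must be positive")
  structure(list(species = species, size_scale = size_scale,
                 seed = as.integer(seed), n_beads = as.integer(n_beads)),
            class = "toy_spec")
}

## Sample beads uniformly inside each lobe, counts proportional to lobe
## volume.  Returns positions plus the subunit id per bead.
sample_lobes <- function(lb, n_total) {
  vol <- lb$r^3
  n_per <- pmax(10L, as.integer(round(n_total * vol / sum(vol))))
  pos <- vector("list", nrow(lb))
  for (i in seq_len(nrow(lb))) {
    n <- n_per[i]
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- lb$r[i] * stats::runif(n)^(1 / 3)
    pos[[i]] <- u * rad +
      matrix(c(lb$cx[i], lb$cy[i], lb$cz[i]), n, 3, byrow = TRUE)
  }
  list(positions = do.call(rbind, pos),
       subunit = rep(lb$subunit, n_per))
}

#' Generate a synthetic toy assembly
#'
#' Builds the bead-cloud model described by a [toy_spec()]:
#' overlapping-sphere lobes sampled with uniform density, deterministic
#' given the spec's seed.  The open and closed dimers share their main
#' lobes and differ only in the position of the two small sub-lobes
#' (separated vs fused), so Rg(open) > Rg(closed); the complexes are
#' built by rigidly docking dimer bodies.
#'
#' @param spec a [toy_spec()].
#' @return A [coordinate_set()]; the attribute `"subunit"` holds an
#'   integer per bead (0 = core body, >0 = docked mobile unit).
#' @export
make_toy_assembly <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  lb <- species_lobes(spec$species)
  smp <- with_seed(spec$seed, sample_lobes(lb, spec$n_beads))
  cs <- coordinate_set(smp$positions * spec$size_scale, weights = 1,
                       label = spec$species)
  attr(cs, "subunit") <- smp$subunit
  cs
}

## --- noise + simulated measurements ----------------------------------

#' q-dependent Gaussian noise model for simulated curves
#'
#' Emulates counting statistics of a beamline frame: the 1-sigma error
#' is `sd(q) = relative_sd_at_low_q * I(q) * (1 + (q / q_half)^2)`, a
#' constant relative error at low q that inflates quadratically beyond
#' `q_half`.
#'
#' @param relative_sd_at_low_q relative error at low q (default 0.01).
#' @param q_half q at which the inflation factor reaches 2, 1/Angstrom.
#' @param seed integer seed for the noise realization.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(relative_sd_at_low_q = 0.01, q_half = 0.2, seed = 1) {
  if (relative_sd_at_low_q < 0 || q_half <= 0)
    stop("noise parameters must be positive")
  structure(list(relative_sd_at_low_q = relative_sd_at_low_q,
                 q_half = q_half, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a noisy measured curve from a model
#'
#' Computes the Debye curve of the model and adds Gaussian noise drawn
#' from the [noise_model()]'s sigma(q); the same sigma is stored
#' truthfully in the returned curve, so chi-square against the true
#' model is ~1 by construction.
#'
#' @param model a [coordinate_set()].
#' @param q_grid q values, 1/Angstrom (default [default_q_grid()]).
#' @param noise a [noise_model()]; `NULL` for a noiseless curve with no
#'   error bars.
#' @param ff a [ff_config()].
#' @return A [scatter_curve()].
#' @export
simulate_noisy_curve <- function(model, q_grid = default_q_grid(),
                                 noise = noise_model(), ff = ff_config()) {
  dc <- debye_curve(model, q_grid, ff = ff)
  if (is.null(noise)) return(dc)
  stopifnot(inherits(noise, "noise_model"))
  sd_q <- noise$relative_sd_at_low_q * abs(dc$intensity) *
    (1 + (q_grid / noise$q_half)^2)
  I_noisy <- with_seed(noise$seed,
                       dc$intensity + stats::rnorm(length(q_grid), 0, sd_q))
  scatter_curve(q_grid, I_noisy, sigma = sd_q,
                label = paste0(dc$label, " +noise"))
}

## --- decoys and time series ------------------------------------------

## Uniform random rotation matrix by random axis + angle in [0, max_deg].
random_rotation <- function(max_deg) {
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  a <- stats::runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Generate rigid-body decoy poses of a docked complex
#'
#' Starting from the true complex of a [toy_spec()] (a species with a
#' mobile docked subunit), produces decoys in which the mobile subunit's
#' beads are rigidly rotated (about the subunit centroid) and translated
#' by random amounts up to the given ranges.  The true pose is element 1
#' of the returned list; the core body beads are shared by all poses.
#'
#' @param true_complex a [toy_spec()] whose species has a docked
#'   subunit (e.g. `"L-complex"`).
#' @param n_decoys number of perturbed poses to generate.
#' @param perturbation numeric length-2: max rotation (degrees), max
#'   translation (Angstrom).
#' @param seed integer seed for the perturbations.
#' @return List of [coordinate_set()], length `n_decoys + 1`, named
#'   `pose_000` (truth) to `pose_<n>`.
#' @export
make_decoy_poses <- function(true_complex, n_decoys,
                             perturbation = c(90, 30), seed = 1) {
  stopifnot(inherits(true_complex, "toy_spec"), n_decoys >= 1)
  rot_max <- perturbation[1]; tr_max <- perturbation[2]
  truth <- make_toy_assembly(true_complex)
  sub <- attr(truth, "subunit")
  if (!any(sub > 0))
    stop("species '", true_complex$species, "' has no mobile docked subunit")
  mobile <- sub == 1
  poses <- vector("list", n_decoys + 1)
  poses[[1]] <- truth
  with_seed(seed + 104729L, for (d in seq_len(n_decoys)) {
    p <- truth$positions
    pm <- p[mobile, , drop = FALSE]
    ctr <- colMeans(pm)
    R <- random_rotation(rot_max)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    shift <- u * stats::runif(1, 0, tr_max)
    pm2 <- sweep(sweep(pm, 2, ctr) %*% t(R), 2, -(ctr + shift))
    p[mobile, ] <- pm2
    cs <- coordinate_set(p, weights = truth$weights,
                         label = sprintf("decoy_%03d", d))
    attr(cs, "subunit") <- sub
    poses[[d + 1]] <- cs
  })
  names(poses) <- c("pose_000", sprintf("pose_%03d", seq_len(n_decoys)))
  poses
}

#' Time series of scattering frames
#'
#' @param times frame times (hours), strictly increasing, all at or
#'   after `dead_time`.
#' @param frames list of [scatter_curve()], one per time.
#' @param dead_time first usable time after mixing (hours).
#' @return An object of class `saxs_series`.
#' @export
time_series <- function(times, frames, dead_time = 0) {
  times <- as.numeric(times)
  if (length(times) != length(frames)) stop("times and frames differ in length")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(times < dead_time)) stop("all times must be >= dead_time")
  lapply(frames, function(f) stopifnot(inherits(f, "saxs_curve")))
  structure(list(times = times, frames = frames, dead_time = dead_time),
            class = "saxs_series")
}

#' @export
print.saxs_series <- function(x, ...) {
  cat(sprintf("saxs_series: %d frames, t in [%g, %g] h (dead time %g h)\n",
              length(x$times), min(x$times), max(x$times), x$dead_time))
  invisible(x)
}

#' Simulate a stopped-flow conversion series
#'
#' Emulates a rapid-mixing experiment in which a large complex converts
#' to a smaller one with first-order kinetics: the frame at time `t` is
#' the mixture `exp(-k t) * I_large + (1 - exp(-k t)) * I_small` plus
#' frame-specific noise.  The generating parameters are attached as the
#' `"manifest"` attribute.
#'
#' @param small,large [toy_spec()]s of the two end states.
#' @param k first-order conversion rate, 1/hour.
#' @param times frame times, hours.
#' @param noise a [noise_model()] (its seed is offset per frame), or
#'   `NULL` for noiseless frames.
#' @param q_grid q values for all frames.
#' @param ff a [ff_config()].
#' @return A [time_series()] with the `"manifest"` attribute.
#' @export
make_stopped_flow_series <- function(small, large, k, times,
                                     noise = noise_model(),
                                     q_grid = default_q_grid(),
                                     ff = ff_config()) {
  stopifnot(inherits(small, "toy_spec"), inherits(large, "toy_spec"))
  if (length(times) < 2) stop("need at least 2 times")
  if (k < 0) stop("k must be non-negative")
  I_small <- debye_curve(make_toy_assembly(small), q_grid, ff = ff)$intensity
  I_large <- debye_curve(make_toy_assembly(large), q_grid, ff = ff)$intensity
  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    w <- exp(-k * times[i])
    I_mix <- w * I_large + (1 - w) * I_small
    if (is.null(noise)) {
      frames[[i]] <- scatter_curve(q_grid, I_mix,
                                   label = sprintf("t=%gh", times[i]))
    } else {
      sd_q <- noise$relative_sd_at_low_q * abs(I_mix) *
        (1 + (q_grid / noise$q_half)^2)
      I_n <- with_seed(noise$seed + 7919L * i,
                       I_mix + stats::rnorm(length(q_grid), 0, sd_q))
      frames[[i]] <- scatter_curve(q_grid, I_n, sigma = sd_q,
                                   label = sprintf("t=%gh", times[i]))
    }
  }
  ts <- time_series(times, frames, dead_time = min(times))
  attr(ts, "manifest") <- list(
    small = small$species, large = large$species, k_per_hour = k,
    noise = if (is.null(noise)) NULL else unclass(noise),
    q_grid = range(q_grid), n_q = length(q_grid))
  ts
}
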