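---
title: "Models and methods behind saxcraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind saxcraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxcraft)
```

saxcraft implements the analysis chain that solution small-angle X-ray
scattering (SAXS) studies of multi-protein assemblies rely on, sized so
that every step runs on a desk machine in seconds to minutes.  The
motivating system is the bacterial tRNA-modification machinery built
from the GTPase MnmE (a ~103 kDa homodimer that switches between an
"open" and a "closed" conformation with its nucleotide state) and the
FAD-binding protein MnmG (a ~140 kDa homodimer), which associate into
an asymmetric 1:1 dimer-of-dimers complex (alpha2-beta2, ~243 kDa) and,
under GTP, an elongated 2:1 complex (alpha4-beta2, ~346 kDa).  All of
those solution states were established by exactly the operations this
package provides: forward scattering from candidate models,
Guinier/p(r)/invariant reduction, conformer-mixture fitting, pose and
stoichiometry selection, ab initio shapes, and time-resolved Rg and
conversion kinetics.

The package ships no experimental data.  Instead the synthetic-data
module generates toy bead assemblies whose sizes land in the regimes of
the real species, and every claim the test suite makes is checked
against closed forms, independent brute-force oracles, or round trips
through the generators.

## Forward model

`debye_curve()` evaluates the Debye sum
$I(q) = \sum_{ij} f_i(q) f_j(q)\, \mathrm{sinc}(q r_{ij})$
over all point pairs of a weighted coordinate model.  In `point` mode
$f_i$ is the point's weight (an electron count for atomic models); in
`uniform-bead` mode each weight is multiplied by the amplitude of a
homogeneous sphere of the configured bead radius,
$3[\sin(qR) - qR\cos(qR)]/(qR)^3$.  The sinc singularity is filled with
1 below $qr < 10^{-8}$.

Two evaluation paths exist and are held to agree to better than
$10^{-6}$ relative: a naive $O(N^2)$ double sum (the oracle, kept for
tests) and a pair-distance histogram with 0.1 Å bins.  Plain histogram
binning is not accurate enough at that width — representative-distance
errors of up to half a bin produce relative errors around $10^{-4}$ —
so the accelerated path carries a second-order within-bin moment
correction: each bin contributes
$W \mathrm{sinc}(q\bar r) + \tfrac12 q^2 M_2\, \mathrm{sinc}''(q\bar r)$
with $\bar r$ the weighted mean distance and $M_2$ the weighted second
central moment in the bin.  That brings the agreement to ${\sim}10^{-7}$
over the full SAXS range.

Hydration is not modelled: curves and model radii of gyration are
"dry".  The full border-layer treatment of experimental fitting
programs is out of scope here, and none of the package's synthetic
checks depend on it; users comparing atomic models against measured
curves should expect model Rg values ~1–3% below hydrated experimental
ones.  The excluded-volume (dummy-solvent) term is likewise omitted and
contrast is a single scalar, because nothing in the package works on an
absolute intensity scale.

`bead_fill_sphere()` provides the uniform-density reference body used
to validate the engine: a cubic-grid fill whose boundary cells carry
fractional weights (the inside fraction of each cell, estimated on a
sub-grid).  With ~2000 beads this reproduces the analytic sphere form
factor within 2% out to $qR = 4$; a hard (unweighted) boundary plateaus
near 4%, which is why the fractional weighting is not optional.

## Guinier analysis

`guinier_fit()` regresses $\ln I$ on $q^2$ with weights $(I/\sigma)^2$
(the delta-method variance of $\ln I$), iterating the window: points
are included while $q\,\mathrm{Rg} \le$ `qmax_rg_limit`, the fit is
repeated, and the window re-derived until stable (at most 20 rounds).
Low-q points are excluded only by an explicit `qmin`; there is no
automatic rejection, so the procedure is deterministic and auditable.

The default window limit is 1.3, the field's standard compromise for
noisy data.  On the *analytic sphere* this window carries a known
systematic: the sphere's $q^4$ term bends the curve below the Guinier
law well inside $q\mathrm{Rg} \le 1.3$, biasing Rg upward by +1.6%
(verified against the closed form; +1.0% at a limit of 1.0, +0.4% at
0.8).  Oracle checks against analytic spheres therefore run the fit in
the strict validity window `qmax_rg_limit = 1.0`; the default is left
at 1.3 because real, noisy, shape-heterogeneous data are what the wider
window is for.

## Invariants and molecular weight

`porod_invariants()` computes $Q = \int q^2 I\,dq$ and
$V_P = 2\pi^2 I(0)/Q$.  The curve is first extended to $q = 0$ with its
Guinier fit (20 synthetic points), and the integral is closed beyond
the truncation point with the Porod-law tail: $K/q_{\mathrm{trunc}}$
with $K$ the mean of $q^4 I$ over the top fifth of the window.  The
tail is not cosmetic — exact arithmetic on the sphere shows plain
truncation at $qR = 8$ leaves $V_P$ 14% high, while the tail-closed
value is within ~4%.

`volume_of_correlation()` computes $V_C = I(0)/\int q I\,dq$ (default
truncation 0.3 Å$^{-1}$) and `mw_estimates()` derives
$Q_R = V_C^2/\mathrm{Rg}$ and the power-law mass
$(Q_R/c)^{1/k}$ (Da, reported in kDa), defaults $c = 0.1231$ Å$^3$/Da,
$k = 1$.  Those constants are an *empirical calibration on measured
protein scattering* and embed hydration-shell and internal-contrast
contributions that idealized uniform-density bodies lack: an exact
homogeneous sphere has $V_C = R^2/2.25$, hence
$Q_R/M = 0.0737$ Å$^3$/Da at protein specific volume 1.21 Å$^3$/Da —
40% below the empirical constant (we confirmed the same shortfall on a
real dry atomic model).  `vc_calibration_uniform()` exports this
closed-form uniform-body constant; use it when the input is a
homogeneous bead model (as the tests do for the 103 kDa globule check),
and the literature default when the input is experimental data.  The
Porod-volume mass uses the conventional 0.6 Da/Å$^3$, with the same
caveat.

## p(r) inversion and Dmax

`pr_invert()` solves
$I(q) = 4\pi \int_0^{D_{max}} p(r)\,\mathrm{sinc}(qr)\,dr$
on 101 equidistant nodes with both endpoints pinned to zero, minimizing
the error-weighted misfit plus $\alpha$ times a second-difference
curvature penalty.  Negative excursions are suppressed by escalating
soft penalties over a few passes and finally hard-floored at $-1\%$ of
$\max p$; the pre-floor negativity is kept as a diagnostic.  When
$\alpha$ is `"auto"` it is chosen at the maximum-curvature knee of the
L-curve over a 15-point log grid, with the penalty scale normalized by
$\mathrm{tr}(A^TWA)/\mathrm{tr}(D^TD)$ so the dimensionless $\alpha$
transfers across problems.  Real-space Rg and I(0) come from the
moments of $p$, so the identity
$\mathrm{Rg}^2 = \int r^2 p\,dr / (2\int p\,dr)$ holds by construction.

`dmax_scan()` replaces perceptual Dmax choice with an explicit rule:
smallest candidate whose residual is within 5% of the grid minimum and
whose pre-floor $p$ stays above $-1\%$ of its maximum.  One
technicality matters: the regularization weight is chosen once (on the
largest candidate) and held fixed across the scan.  Letting the
L-curve pick a different knee per candidate makes the residuals jump
for numerical rather than structural reasons, and on noiseless data the
5%-of-minimum rule then selects essentially at random along the
plateau.  With a fixed $\alpha$ the residual is monotone down to the
true extent and flat beyond it, and the rule lands one grid step above
the true Dmax at worst.  Choices at the grid boundary are flagged
`at_grid_edge`.

## Mixture fitting

`fit_mixture()` resamples the component curves onto the target grid
(linear interpolation, out-of-range points dropped with a message) and
solves the error-weighted non-negative least-squares problem over the
raw amplitudes with Lawson–Hanson NNLS, then normalizes to fractions.
Weights are intensity-share fractions; for equal-mass conformers (the
open/closed pair, which is the motivating use) these equal volume
fractions, and a warning is emitted when components differ in forward
scattering so the caller knows the distinction is live.  The additive
background term is off by default and enters as a signed column pair
when enabled.  Component collinearity (condition number above 1e10) is
flagged, with weights still returned.

The supporting identity
$\mathrm{Rg}_{app}^2 = \sum w_i I_{0i} \mathrm{Rg}_i^2 / \sum w_i I_{0i}$
(`apparent_rg_of_mixture()`) interprets Guinier fits of mixtures, e.g.
the apparent-Rg traces of a converting two-state series.

## Model scoring and selection

`score_model()` computes the reduced
$\chi^2 = \frac{1}{N-m}\sum [(I_e - cI_m - b)/\sigma]^2$ with the
analytic optimal scale (and constant, if enabled; $m$ = 1 or 2), plus
an L1 R-factor $\sum|I_e - cI_m - b| / \sum|I_e|$.  The R-factor is a
declared stand-in for the fitting-parameter R reported alongside chi2
in the experimental literature, whose exact formula is not printed
there; its values are comparable in spirit but not numerically, and
chi2 carries the quantitative weight everywhere in this package.

`rank_poses()` reproduces the docking-ensemble selection step: an Rg
prefilter (default window ±5 Å around the experimental Guinier Rg,
exclusions logged, all-excluded is an error carrying the log), Debye
curves for the survivors, chi2 ordering with ties broken by R-factor
then label — fully deterministic and stable under permutation of the
input.  `discriminate_stoichiometry()` applies the same scoring across
labelled assembly hypotheses and reports the chi2 margin
(second-best/best), declaring discrimination at a margin of 3 by
default; the synthetic 2:1-vs-inverted-control experiment yields
margins above 100, the package's analogue of the decisive chi2 gap
between correct and wrong stoichiometric models of the real complex.

## Ab initio shapes

`make_lattice()` fills a search sphere with touching beads (hcp or
cubic, spacing twice the bead radius); `anneal_shape()` runs Metropolis
single-bead flips under a geometric temperature schedule on the
objective chi2 + looseness + disconnection, where looseness is the
fraction of occupied beads with fewer than 3 occupied neighbors (weight
1) and disconnection is one minus the largest-component fraction
(weight 5, recomputed once per temperature).  These penalty forms are
declared surrogates for the compactness terms of the established
annealers, not reimplementations.  The initial state is a central blob
matching the curve's Guinier Rg; proposals are restricted to the
cluster surface (occupied beads and empty neighbors), which is what
keeps stray disconnected beads from accumulating between connectivity
updates.  Temperature starts at a tenth of the initial objective,
cools by 0.85, and stops at $10^{-4}$ of the start or when acceptance
drops below 1% per sweep.  The best-visited state is returned; a final
largest-component fraction below 95% flags the model `disconnected`
rather than silently accepting it (a genuinely two-lobed target such as
a dumbbell *should* return flagged).

Two numerical points.  First, scattering updates are incremental
through a pair-distance histogram with 0.05 Å bins — at SAXS q values
the binning phase error is below 0.01 rad, i.e. the incremental curve
is exact for practical purposes.  Second, the objective's errors are
floored at 0.1% of the peak intensity: synthetic noise models
proportional to $I$ vanish at form-factor minima while the bead
discretization error there does not, and without the floor the minima
dominate the whole fit.  Reconstruction quality is scored with
`shape_agreement()`, a normalized-spatial-discrepancy-style metric:
principal-axes superposition (best of the four proper axis-sign
conventions), symmetric mean nearest-neighbor distance, normalized by
the sets' own mean nearest-neighbor spacing — 0 for identical sets,
below ~1 for similar shapes, above 1 for dissimilar ones (a sphere and
an equal-Rg dumbbell score ~1.5).  `average_runs()` aligns multiple
reconstructions (principal axes into the reference's lattice frame,
centroid-only for near-degenerate inertia tensors), snaps to lattice
sites and keeps sites above an occupancy-frequency threshold — a
deliberately simple consensus in place of multi-run averaging suites.

## Kinetics

`series_rg()` condenses a stopped-flow series into a per-frame Guinier
trace, reporting failed frames with their reason instead of dropping
them.  `fractions_from_series()` fits every frame as a two-component
mixture of end-member curves and returns the large-species fraction
trace.  `fit_conversion()` models that trace as
$f(t) = f_0 e^{-kt}$ — pseudo-first-order substrate consumption driving
the large-to-small conversion — by weighted Levenberg–Marquardt from a
log-linear start; flat traces return a `non_identifiable` flag rather
than a spurious rate.  Single-exponential (not Michaelis–Menten)
kinetics is the deliberate model choice: the motivating experiment used
near-stoichiometric substrate and reports only a half-conversion time,
which cannot identify two more parameters.  Sub-dead-time assembly is
treated as instantaneous, so $f_0$ is the fraction at the dead time.
All kinetic quantities use hours (rates in 1/h) end to end.

## Synthetic data: what it emulates, and what it does not

`make_toy_assembly()` builds each species from overlapping spherical
lobes sampled with uniform bead density (about 800 beads), fully
deterministic given the seed, with the caller's RNG state untouched.
The lobe geometry was tuned once, against the analytic
two-moment formula for sphere assemblies, so the generated Rg values
land on the regimes of the real species — open dimer 38.6 Å vs closed
37.2 Å (shared main lobes, sub-lobes separated vs fused), 1:1 complex
52.3 Å (a dimer docked asymmetrically on one end of the larger dimer,
giving the L shape), elongated 2:1 complex 67.4 Å (linear A–B–A, Rg
ratio to the L complex 1.28, matching the real pair's 67.4/52.3), the
inverted B–A–B control near 58 Å, and a two-armed tRNA-like L of
23.5 Å.  The defaults — q grid of 400 points on [0.01, 0.35] Å$^{-1}$,
1% relative noise at low q inflating as $1 + (q/0.2)^2$, 2% noise and
the fraction grid {0.1, 0.25, 0.5, 0.75, 0.9} for mixture recovery, the
0.88/0.12 conformer scenario, rate $\ln 2 / 2$ h$^{-1}$ (half-life
2 h) with frames spanning 0.05–24 h — are the study conditions of the
synthetic experiments and are not adjusted per run.

These toys are *not* protein-realistic: homogeneous density, no
internal contrast, no hydration shell, no inter-domain flexibility, and
multiplicative noise rather than counting statistics.  Consequently,
passing tests demonstrate that the inference chain recovers what the
generators put in — sizes, fractions, poses, shapes, rates — under
honest noise; they do not demonstrate calibration against real beamline
data, which is exactly where the empirical MW constants (above) and the
hydration caveat enter.

## Problem sizes

The shipped checks run the Debye oracle on 500-point clouds, mixture
recovery at 100 replicates per fraction, pose selection over 51-model
ensembles on a 200-point grid, annealing on lattices of ~500–1400
candidate sites for 3 seeds per target, and the kinetic round trip on
9 frames of 200 points — chosen so the full suite and the acceptance
computation each complete in a few minutes on one core while leaving
every recovery criterion comfortably inside its tolerance.
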