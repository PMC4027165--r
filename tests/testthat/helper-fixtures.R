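# Shared fixture builders; everything generated in code at test time.

# standard q grid used across tests unless a test needs otherwise
test_q <- function(n = 200, qmin = 0.005, qmax = 0.35) {
  seq(qmin, qmax, length.out = n)
}

# analytic two-sphere dumbbell curve: radii r, centers d apart
dumbbell_curve <- function(q, r = 15, d = 50, i0_scale = 1) {
  amp2 <- saxcraft:::sphere_amplitude(q, r)^2
  scatter_curve(q, i0_scale * amp2 * 2 * (1 + saxcraft:::sinc(q * d)),
                label = sprintf("dumbbell r=%g d=%g", r, d))
}

# ground-truth dumbbell bead model matching dumbbell_curve
dumbbell_beads <- function(r = 15, d = 50, spacing = 5) {
  half <- bead_fill_sphere(r, spacing)
  coordinate_set(rbind(sweep(half$positions, 2, c(-d / 2, 0, 0), `+`),
                       sweep(half$positions, 2, c(d / 2, 0, 0), `+`)),
                 weights = c(half$weights, half$weights),
                 label = "dumbbell beads")
}

# minimal PDB text with C/N/O ATOMs, one H, and a water HETATM
write_test_pdb <- function(path, with_h = TRUE, with_water = TRUE) {
  lines <- c(
    "HEADER    TEST",
    "ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00  0.00           C",
    "ATOM      2  N   ALA A   1      12.500  12.000  13.000  1.00  0.00           N",
    "ATOM      3  O   ALA A   1      14.000  12.000  13.000  1.00  0.00           O")
  if (with_h)
    lines <- c(lines,
      "ATOM      4  HA  ALA A   1      11.500  12.500  13.000  1.00  0.00           H")
  if (with_water)
    lines <- c(lines,
      "HETATM    5  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O")
  writeLines(c(lines, "END"), path)
  path
}

# fraction-weight trace simulated directly (no scattering), for the
# kinetic fitter in isolation
conversion_trace <- function(k, times, f0 = 1, noise_sd = 0, seed = 1) {
  f <- f0 * exp(-k * times)
  if (noise_sd > 0) {
    set.seed(seed)
    f <- pmin(pmax(f + rnorm(length(times), 0, noise_sd), 0), 1)
  }
  data.frame(time = times, fraction_large = f)
}
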