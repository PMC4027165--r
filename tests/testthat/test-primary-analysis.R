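test_that("Guinier fit inverts an exact Guinier law to 4 significant digits", {
  q <- test_q(300, 0.002, 0.2)
  rg <- 38.6; i0 <- 100
  cv <- scatter_curve(q, i0 * exp(-q^2 * rg^2 / 3))
  gf <- guinier_fit(cv)
  expect_equal(gf$rg, rg, tolerance = 1e-4)
  expect_equal(gf$i0, i0, tolerance = 1e-4)
  expect_lte(gf$qmax_rg_product, 1.3 + 1e-9)
})

test_that("Guinier fit on the analytic sphere recovers R sqrt(3/5)", {
  q <- test_q(400, 0.002)
  sc <- sphere_curve(30, q, i0 = 100)
  # strict-validity window for the analytic oracle; the wider 1.3
  # default carries a known upward bias on spheres (checked below)
  gf <- guinier_fit(sc, qmax_rg_limit = 1.0)
  expect_equal(gf$rg, 30 * sqrt(3 / 5), tolerance = 0.25 / 23.24)
  gf13 <- guinier_fit(sc, qmax_rg_limit = 1.3)
  expect_gt(gf13$rg, gf$rg)          # bias grows with the window
  expect_lt(gf13$rg / (30 * sqrt(3 / 5)) - 1, 0.02)
})

test_that("flat curves give a degenerate Guinier fit", {
  cv <- scatter_curve(test_q(50), rep(7, 50))
  gf <- guinier_fit(cv)
  expect_true(gf$degenerate)
  expect_equal(gf$rg, 0)
})

test_that("Porod volume of a sphere lands within 10% of 4/3 pi R^3", {
  q <- test_q(400, 0.005)
  sc <- sphere_curve(30, q, i0 = 100)
  pv <- porod_invariants(sc, q_trunc = 8 / 30)
  expect_lt(abs(pv$porod_volume / (4 / 3 * pi * 30^3) - 1), 0.10)
})

test_that("Porod and correlation volumes are intensity-scale invariant", {
  q <- test_q(400, 0.005)
  sc <- sphere_curve(30, q, i0 = 100)
  sc2 <- scatter_curve(q, 2 * sc$intensity)
  expect_equal(porod_invariants(sc2, 0.25)$porod_volume,
               porod_invariants(sc, 0.25)$porod_volume, tolerance = 1e-9)
  expect_equal(volume_of_correlation(sc2), volume_of_correlation(sc),
               tolerance = 1e-9)
})

test_that("pure-noise curves are rejected as non-physical", {
  set.seed(8)
  q <- test_q(100)
  cv <- scatter_curve(q, rnorm(100, 0, 1) + 0.01)
  expect_error(porod_invariants(cv, 0.25))
})

test_that("p(r) inversion of the sphere matches the closed-form distribution", {
  q <- test_q(400, 0.005)
  sc <- sphere_curve(30, q, i0 = 100)
  pr <- pr_invert(sc, dmax = 60)
  # closed form: p(r) proportional to r^2 (1 - 3x/4 + x^3/16), x = r/R
  x <- pr$r_grid / 30
  p_true <- pr$r_grid^2 * (1 - 3 * x / 4 + x^3 / 16)
  p_true[pr$r_grid > 60] <- 0
  s <- sum(pr$p_values * p_true) / sum(p_true^2)
  nrms <- sqrt(mean((pr$p_values - s * p_true)^2)) / max(s * p_true)
  expect_lt(nrms, 0.05)
  expect_equal(pr$rg_real, 30 * sqrt(3 / 5), tolerance = 0.3 / 23.24)
  expect_equal(pr$i0_real, 100, tolerance = 0.02)
  # pinned endpoints and the moment identity
  expect_equal(pr$p_values[1], 0)
  expect_equal(pr$p_values[length(pr$p_values)], 0)
  m0 <- saxcraft:::trapz_int(pr$r_grid, pr$p_values)
  m2 <- saxcraft:::trapz_int(pr$r_grid, pr$r_grid^2 * pr$p_values)
  expect_equal(pr$rg_real, sqrt(m2 / (2 * m0)), tolerance = 1e-6)
})

test_that("stronger regularization monotonically degrades the data fit", {
  q <- test_q(200, 0.005)
  sc <- sphere_curve(25, q, i0 = 10)
  alphas <- c(1e-4, 1e-2, 1, 100)
  chis <- vapply(alphas, function(a) pr_invert(sc, 55, alpha = a)$chi2,
                 numeric(1))
  expect_true(all(diff(chis) >= -1e-12))
})

test_that("p(r) back-transform reproduces a noisy curve at chi2 ~ 1", {
  # a smooth multi-lobe body: no deep form-factor minima in range, as
  # for real protein data
  m <- make_toy_assembly(toy_spec("closed-dimer"))
  cv <- simulate_noisy_curve(m, test_q(300, 0.01),
                             noise = noise_model(0.01, seed = 21))
  pr <- pr_invert(cv, dmax = 110)
  expect_lt(pr$chi2, 2)
  expect_gt(pr$chi2, 0.4)
})

test_that("dmax_scan brackets the true extent for sphere and dumbbell", {
  q <- test_q(400, 0.005)
  sc <- sphere_curve(30, q, i0 = 100)
  ds <- dmax_scan(sc, seq(40, 100, by = 5))
  expect_gte(ds$dmax, 55)
  expect_lte(ds$dmax, 65)
  expect_false(ds$at_grid_edge)
  expect_true(is.data.frame(ds$table))

  db <- dumbbell_curve(q, r = 15, d = 80)     # extent 110 A
  ds2 <- dmax_scan(db, seq(80, 140, by = 10))
  expect_gte(ds2$dmax, 100)
  expect_lte(ds2$dmax, 120)

  ds3 <- dmax_scan(sc, c(40, 45, 50))          # grid below the true 60
  expect_true(ds3$at_grid_edge)
})

test_that("volume of correlation converges with quadrature density", {
  vc1 <- volume_of_correlation(sphere_curve(30, test_q(200, 0.005), i0 = 1))
  vc2 <- volume_of_correlation(sphere_curve(30, test_q(800, 0.005), i0 = 1))
  expect_lt(abs(vc1 / vc2 - 1), 0.005)
})

test_that("volume_of_correlation reports truncation sensitivity", {
  sc <- sphere_curve(30, test_q(400, 0.005), i0 = 1)
  expect_message(volume_of_correlation(sc, verbose = TRUE), "delta")
})

test_that("mw_estimates applies the power law and its scalings", {
  inv <- mw_estimates(vc = sqrt(12310 * 20), rg = 20)  # qr = 12310 A^3
  expect_equal(inv$qr, 12310, tolerance = 1e-9)
  expect_equal(inv$mw_vc, 100, tolerance = 1e-9)       # kDa
  # doubling rg at fixed vc halves qr
  inv2 <- mw_estimates(vc = sqrt(12310 * 20), rg = 40)
  expect_equal(inv2$qr, inv$qr / 2, tolerance = 1e-12)
  expect_error(mw_estimates(-1, 10))
})

test_that("uniform-body calibration recovers a 103 kDa globule within 15%", {
  # sphere with the volume of a 103 kDa protein (1.21 A^3/Da)
  R <- (103000 * 1.21 / (4 / 3 * pi))^(1 / 3)
  q <- test_q(400, 0.005)
  sc <- sphere_curve(R, q, i0 = 50)
  gf <- guinier_fit(sc, qmax_rg_limit = 1.0)
  vc <- volume_of_correlation(sc, guinier = gf)
  inv <- mw_estimates(vc, gf$rg, c_protein = vc_calibration_uniform())
  expect_lt(abs(inv$mw_vc / 103 - 1), 0.15)
})

test_that("real-space and Guinier Rg agree within 3% on noiseless globules", {
  blob <- bead_fill_sphere(26, 4)
  q <- test_q(300, 0.005)
  cv <- debye_curve(blob, q)
  gf <- guinier_fit(cv, qmax_rg_limit = 1.0)
  pr <- pr_invert(cv, dmax = 54)
  expect_lt(abs(pr$rg_real / gf$rg - 1), 0.03)
})
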