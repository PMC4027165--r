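test_that("Debye curve matches closed-form point configurations", {
  one <- coordinate_set(matrix(0, 1, 3), weights = 2)
  q <- test_q(20)
  expect_equal(debye_curve(one, q)$intensity, rep(4, 20))

  pair <- coordinate_set(rbind(c(0, 0, 0), c(10, 0, 0)), weights = 1)
  dc <- debye_curve(pair, c(1e-5, pi / 10), method = "naive")
  expect_equal(dc$intensity[1], 4, tolerance = 1e-6)
  expect_equal(dc$intensity[2], 2, tolerance = 1e-12)  # sinc(pi) = 0
})

test_that("histogram-accelerated Debye matches the naive double sum", {
  set.seed(7)
  cloud <- coordinate_set(matrix(rnorm(300 * 3, sd = 15), ncol = 3),
                          weights = runif(300, 0.5, 2))
  q <- test_q(60)
  a <- debye_curve(cloud, q, method = "histogram")
  b <- debye_curve(cloud, q, method = "naive")
  expect_lt(max(abs(a$intensity - b$intensity) / b$intensity), 1e-6)

  ff <- ff_config("uniform-bead", bead_radius = 3)
  a2 <- debye_curve(cloud, q, ff = ff, method = "histogram")
  b2 <- debye_curve(cloud, q, ff = ff, method = "naive")
  expect_lt(max(abs(a2$intensity - b2$intensity) / b2$intensity), 1e-6)
})

test_that("sphere_curve has the analytic normalization, minimum and Guinier limit", {
  q <- seq(1e-4, 0.5, length.out = 5000)
  sc <- sphere_curve(30, q)
  expect_equal(sc$intensity[1], 1, tolerance = 1e-5)
  expect_true(all(sc$intensity <= 1 + 1e-12))
  # first minimum of the form factor at qR ~ 4.4934 (root of tan x = x)
  x <- q * 30
  win <- which(x > 3 & x < 6)
  expect_equal(x[win][which.min(sc$intensity[win])], 4.4934, tolerance = 1e-3)
  # low-q expansion 1 - q^2 Rg^2 / 3 with Rg = R sqrt(3/5)
  rg2 <- 30^2 * 3 / 5
  lowq <- q[q * 30 < 0.3]
  expect_equal(sc$intensity[seq_along(lowq)], 1 - lowq^2 * rg2 / 3,
               tolerance = 1e-3)
  expect_error(sphere_curve(-1, q), "positive")
})

test_that("bead-filled sphere reproduces the analytic form factor", {
  fill <- bead_fill_sphere(30, 3.84)
  q <- seq(0.005, 4 / 30, length.out = 50)
  dc <- debye_curve(fill, q)
  an <- sphere_curve(30, q, i0 = sum(fill$weights)^2)
  expect_lt(max(abs(dc$intensity / an$intensity - 1)), 0.02)
})

test_that("debye intensity is invariant under rigid motion and bounded by I(0)", {
  set.seed(2)
  cloud <- coordinate_set(matrix(rnorm(150 * 3, sd = 12), ncol = 3), weights = 1)
  q <- test_q(40)
  base <- debye_curve(cloud, q)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- coordinate_set(sweep(cloud$positions %*% R, 2, c(5, -3, 11), `+`),
                          weights = 1)
  expect_equal(debye_curve(moved, q)$intensity, base$intensity,
               tolerance = 1e-9)

  blob <- bead_fill_sphere(20, 4)
  dcb <- debye_curve(blob, test_q(80))
  expect_true(all(dcb$intensity <= sum(blob$weights)^2 + 1e-9))
})

test_that("coarse_grain conserves weight and preserves Rg at fine spacing", {
  set.seed(3)
  cloud <- coordinate_set(matrix(rnorm(400 * 3, sd = 15), ncol = 3),
                          weights = runif(400, 0.5, 2))
  # spacing below any interpoint distance: identity in count
  cg_id <- coarse_grain(cloud, 1e-4)
  expect_equal(nrow(cg_id$positions), 400)

  corners <- coordinate_set(as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10,
                            weights = 1)
  cg1 <- coarse_grain(corners, 25)
  expect_equal(nrow(cg1$positions), 1)
  expect_equal(sum(cg1$weights), 8)
  expect_equal(as.numeric(cg1$positions), c(5, 5, 5))

  rg0 <- rg_of_coords(cloud)
  cg <- coarse_grain(cloud, rg0 / 10)
  expect_lt(abs(rg_of_coords(cg) / rg0 - 1), 0.02)
  expect_equal(sum(cg$weights), sum(cloud$weights))
})

test_that("rg_of_coords matches closed forms and is rigid-motion invariant", {
  expect_equal(rg_of_coords(coordinate_set(matrix(1, 1, 3), weights = 3)), 0)
  pair <- coordinate_set(rbind(c(0, 0, 0), c(10, 0, 0)), weights = 1)
  expect_equal(rg_of_coords(pair), 5)

  set.seed(4)
  cloud <- coordinate_set(matrix(rnorm(90), ncol = 3), weights = runif(30))
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  moved <- coordinate_set(sweep(cloud$positions %*% R, 2, c(-7, 2, 4), `+`),
                          weights = cloud$weights)
  expect_equal(rg_of_coords(moved), rg_of_coords(cloud), tolerance = 1e-12)
})

test_that("Guinier fit of a Debye curve recovers the model Rg within 1%", {
  set.seed(5)
  cloud <- coordinate_set(matrix(rnorm(500 * 3, sd = 14), ncol = 3), weights = 1)
  rg_true <- rg_of_coords(cloud)
  q <- seq(0.002, 1 / rg_true, length.out = 150)   # q Rg <= 1
  gf <- guinier_fit(debye_curve(cloud, q), qmax_rg_limit = 1.0)
  expect_lt(abs(gf$rg / rg_true - 1), 0.01)
})
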