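test_that("noiseless first-order data invert exactly to the generating rate", {
  k <- log(2) / 2                       # half-life 2 h
  times <- c(0.05, 0.5, 1, 2, 4, 8, 16, 24)
  kf <- fit_conversion(conversion_trace(k, times))
  expect_equal(kf$half_life, 2, tolerance = 1e-6)
  expect_equal(kf$k_hyd, k, tolerance = 1e-6)
  expect_equal(kf$f_large[times == 2], kf$f0 / 2, tolerance = 1e-6)
  expect_false(kf$non_identifiable)
})

test_that("rate recovery from noisy traces is unbiased within 3%", {
  k <- log(2) / 2
  times <- seq(0.5, 24, length.out = 9)
  ks <- vapply(1:100, function(s) {
    set.seed(s)
    f_true <- exp(-k * times)
    sdv <- pmax(0.05 * f_true, 0.005)       # 5% relative, floored
    f <- pmax(f_true + rnorm(length(times), 0, sdv), 0)
    fit_conversion(data.frame(time = times, fraction_large = f,
                              sd = sdv))$k_hyd
  }, numeric(1))
  expect_lt(abs(mean(ks) / k - 1), 0.03)
  expect_lt(sd(ks) / k, 0.10)
})

test_that("flat fraction traces are flagged non-identifiable", {
  obs <- data.frame(time = 1:6, fraction_large = rep(0.4, 6))
  kf <- fit_conversion(obs)
  expect_true(kf$non_identifiable)
  expect_true(is.na(kf$k_hyd))
})

test_that("per-frame mixture fractions recover the generating trace exactly", {
  small <- toy_spec("L-complex"); large <- toy_spec("extended-3-lobe")
  k <- log(2) / 2
  times <- c(0.1, 0.5, 1, 2, 4, 8, 16)
  ser <- make_stopped_flow_series(small, large, k, times, noise = NULL,
                                  q_grid = default_q_grid(200))
  q <- default_q_grid(200)
  em_s <- debye_curve(make_toy_assembly(small), q)
  em_l <- debye_curve(make_toy_assembly(large), q)
  fr <- fractions_from_series(ser, em_s, em_l)
  expect_equal(fr$fraction_large, exp(-k * times), tolerance = 5e-4)
  # swapped end members give the complementary trace
  fr_sw <- fractions_from_series(ser, em_l, em_s)
  expect_equal(fr_sw$fraction_large, 1 - exp(-k * times), tolerance = 5e-4)
})

test_that("the full pipeline recovers the rate within 10% at 2% noise", {
  small <- toy_spec("L-complex"); large <- toy_spec("extended-3-lobe")
  k <- log(2) / 2
  times <- c(0.05, 0.25, 0.5, 1, 2, 4, 8, 16, 24)
  ser <- make_stopped_flow_series(small, large, k, times,
                                  noise = noise_model(0.02, seed = 7),
                                  q_grid = default_q_grid(200))
  q <- default_q_grid(200)
  em_s <- debye_curve(make_toy_assembly(small), q)
  em_l <- debye_curve(make_toy_assembly(large), q)
  kf <- fit_conversion(fractions_from_series(ser, em_s, em_l))
  expect_lt(abs(kf$k_hyd / k - 1), 0.10)
})

test_that("Guinier traces are flat for constant series, monotone for transitions", {
  ctrl_spec <- toy_spec("open-dimer")                  # Rg ~ 38 A control
  q <- default_q_grid(200)
  frames <- lapply(1:6, function(i)
    simulate_noisy_curve(make_toy_assembly(ctrl_spec), q,
                         noise_model(0.01, seed = 30 + i)))
  ser <- time_series(1:6, frames)
  tr <- series_rg(ser)
  expect_true(all(tr$status == "ok"))
  # no trend: slope CI of rg ~ time contains zero
  fit <- lm(rg ~ time, data = tr)
  ci <- confint(fit)["time", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  # per-frame scatter consistent with the fit errors
  expect_lt(sd(tr$rg), 3 * stats::median(tr$sd))

  # two-state transition: apparent Rg moves between the end-member Rgs
  small <- toy_spec("L-complex"); large <- toy_spec("extended-3-lobe")
  ser2 <- make_stopped_flow_series(small, large, log(2) / 2,
                                   c(0.1, 1, 4, 8, 16, 24),
                                   noise = noise_model(0.01, seed = 9),
                                   q_grid = q)
  tr2 <- series_rg(ser2)
  rg_small <- rg_of_coords(make_toy_assembly(small))
  rg_large <- rg_of_coords(make_toy_assembly(large))
  expect_true(all(tr2$rg > rg_small - 2 & tr2$rg < rg_large + 2))
  expect_lt(tr2$rg[length(tr2$rg)], tr2$rg[1])
})

test_that("apparent Rg of a two-state frame follows the mixture quadrature", {
  small <- make_toy_assembly(toy_spec("L-complex"))
  large <- make_toy_assembly(toy_spec("extended-3-lobe"))
  q <- seq(0.002, 0.035, length.out = 100)      # strict Guinier region
  w <- 0.5
  I_mix <- w * debye_curve(large, q)$intensity +
    (1 - w) * debye_curve(small, q)$intensity
  gf <- guinier_fit(scatter_curve(q, I_mix), qmax_rg_limit = 0.8)
  rg_pred <- apparent_rg_of_mixture(
    c(w, 1 - w), c(rg_of_coords(large), rg_of_coords(small)),
    c(sum(large$weights)^2, sum(small$weights)^2))
  expect_lt(abs(gf$rg / rg_pred - 1), 0.02)
})

test_that("single-frame series yield a single-entry trace", {
  q <- default_q_grid(150)
  fr <- simulate_noisy_curve(make_toy_assembly(toy_spec("open-dimer")), q,
                             noise_model(0.01, seed = 77))
  ser <- time_series(0.5, list(fr))
  tr <- series_rg(ser)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$status, "ok")
})
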