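test_that("identical model and data score chi2 = 0 and R-factor = 0", {
  q <- test_q(100)
  cv <- scatter_curve(q, 50 * exp(-q^2 * 400), sigma = rep(0.5, 100))
  sc <- score_model(cv, cv)
  expect_equal(sc$chi2, 0, tolerance = 1e-20)
  expect_equal(sc$r_sas, 0, tolerance = 1e-12)
  expect_equal(sc$scale, 1, tolerance = 1e-12)
})

test_that("chi2 of the true model against noise at stated sigma is ~1", {
  q <- seq(0.01, 0.35, length.out = 400)
  I_true <- 80 * exp(-q^2 * 350) + 0.3
  sig <- 0.01 * I_true * (1 + (q / 0.2)^2)
  chis <- vapply(1:20, function(s) {
    set.seed(s + 100)
    noisy <- scatter_curve(q, I_true + rnorm(400, 0, sig), sigma = sig)
    score_model(noisy, scatter_curve(q, I_true))$chi2
  }, numeric(1))
  expect_true(all(chis > 0.8 & chis < 1.2))
  expect_lt(abs(mean(chis) - 1), 0.05)
})

test_that("chi2 is invariant to rescaling of the model curve", {
  q <- test_q(100)
  set.seed(12)
  I_true <- 40 * exp(-q^2 * 300)
  exp_cv <- scatter_curve(q, I_true * (1 + rnorm(100, 0, 0.01)),
                          sigma = 0.01 * I_true)
  m1 <- score_model(exp_cv, scatter_curve(q, I_true))
  m9 <- score_model(exp_cv, scatter_curve(q, 9 * I_true))
  expect_equal(m1$chi2, m9$chi2, tolerance = 1e-9)
  expect_equal(m9$scale, m1$scale / 9, tolerance = 1e-9)
})

test_that("rank_poses places the true pose first and logs exclusions", {
  poses <- make_decoy_poses(toy_spec("L-complex"), 15,
                            perturbation = c(90, 30), seed = 3)
  q <- default_q_grid(150)
  tgt <- debye_curve(poses[[1]], q)
  rk <- rank_poses(tgt, poses, rg_window = 5)
  expect_equal(rk$table$label[1], "pose_000")
  expect_true(all(diff(rk$table$chi2) >= 0))
  expect_equal(nrow(rk$table) + nrow(rk$filter_log), length(poses))
  if (nrow(rk$filter_log) > 0)
    expect_true(all(grepl("window", rk$filter_log$reason)))
})

test_that("duplicated true poses tie on chi2 and order by label", {
  poses <- make_decoy_poses(toy_spec("L-complex"), 5,
                            perturbation = c(60, 20), seed = 4)
  dup <- c(poses, list(pose_dup = poses[[1]]))
  q <- default_q_grid(120)
  tgt <- debye_curve(poses[[1]], q)
  rk <- rank_poses(tgt, dup, rg_window = 10)
  expect_equal(rk$table$chi2[1], rk$table$chi2[2], tolerance = 1e-12)
  expect_equal(rk$table$label[1:2], sort(c("pose_000", "pose_dup")))
})

test_that("a tight Rg window excludes far-off decoys, all-excluded errors", {
  poses <- make_decoy_poses(toy_spec("L-complex"), 10,
                            perturbation = c(90, 40), seed = 5)
  q <- default_q_grid(120)
  tgt <- debye_curve(poses[[1]], q)
  rk <- rank_poses(tgt, poses, rg_window = 1.5)
  expect_gt(nrow(rk$filter_log), 0)
  # an impossible window excludes everything and carries the log
  err <- tryCatch(rank_poses(tgt, poses[2:6], rg_window = 1e-6),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_true(!is.null(err$filter_log))
})

test_that("ranking is stable under permutation of the model list", {
  poses <- make_decoy_poses(toy_spec("L-complex"), 8,
                            perturbation = c(45, 15), seed = 6)
  q <- default_q_grid(100)
  tgt <- debye_curve(poses[[1]], q)
  r1 <- rank_poses(tgt, poses, rg_window = 20)
  set.seed(9); perm <- sample(length(poses))
  r2 <- rank_poses(tgt, poses[perm], rg_window = 20)
  expect_equal(r1$table$label, r2$table$label)
  expect_equal(r1$table$chi2, r2$table$chi2, tolerance = 1e-12)
})

test_that("wrong stoichiometries score at least 10x the true model", {
  cands <- list(
    alpha4beta2 = make_toy_assembly(toy_spec("extended-3-lobe")),
    alpha2beta2 = make_toy_assembly(toy_spec("L-complex")),
    one_to_two = make_toy_assembly(toy_spec("inverted-1:2")))
  q <- default_q_grid(150)
  exp_cv <- simulate_noisy_curve(cands$alpha4beta2, q,
                                 noise_model(0.01, seed = 5))
  rep <- discriminate_stoichiometry(exp_cv, cands)
  expect_equal(rep$winner, "alpha4beta2")
  expect_gte(rep$margin, 10)
  expect_true(rep$discriminated)
})

test_that("identical candidates cannot be discriminated", {
  m <- make_toy_assembly(toy_spec("L-complex"))
  q <- default_q_grid(100)
  exp_cv <- simulate_noisy_curve(m, q, noise_model(0.01, seed = 6))
  rep <- discriminate_stoichiometry(exp_cv, list(a = m, b = m))
  expect_equal(rep$margin, 1, tolerance = 1e-9)
  expect_false(rep$discriminated)
})
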