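test_that("scenario-1 generation reproduces the stated population", {
  spec <- scenario_spec("S1")
  d <- generate_dataset(spec, 10000, seed = 301)
  expect_equal(nrow(d), 10000)
  expect_named(d, c("id", paste0("x", 1:5), "dose", "E", "T"))
  # rejection excludes at most ~40-45% of proposed covariate vectors
  expect_lte(attr(d, "rejection_rate"), 0.45)
  # outcome rates in the stated ranges
  expect_gte(mean(d$E), 0.5); expect_lte(mean(d$E), 0.7)
  expect_gte(mean(d$T), 0.1); expect_lte(mean(d$T), 0.3)
  # every retained patient satisfies both positivity constraints
  expect_true(all(1 + 0.23 * d$x1 + 0.61 * d$x2 + 1.69 * d$x4 +
                    0.5 * d$x5 > 0))
  expect_true(all(1 + 0.03 * d$x1 + 0.6 * d$x2 - 0.42 * d$x4 +
                    1.04 * d$x5 > 0))
  # determinism under a fixed seed
  d2 <- generate_dataset(spec, 500, seed = 302)
  d3 <- generate_dataset(spec, 500, seed = 302)
  expect_identical(d2, d3)
})

test_that("the true joint matches closed-form probit values", {
  spec <- scenario_spec("S1")
  j <- true_joint(spec, matrix(0, 1, 5), 0)
  expect_equal(j$pE, 0.5, tolerance = 1e-9)
  expect_equal(j$pT, pnorm(-1.386), tolerance = 1e-9)
  # Frechet feasibility of the alpha = 0.8 joint across random patients
  set.seed(311)
  x <- matrix(rnorm(100), 20, 5)
  j <- true_joint(spec, x, runif(20, -1, 1))
  fb <- frechet_bounds(j$pE, j$pT)
  expect_true(all(j$p11 >= fb$lower - 1e-9 & j$p11 <= fb$upper + 1e-9))
})

test_that("oracle dosing maximizes the true utility", {
  spec <- scenario_spec("S1")
  grid <- dose_grid()
  cfg2 <- utility_config(utility_matrix(0.5, 0.5))
  # all-zero patient: stationary point at 1.386 / 2
  expect_lt(abs(oracle_rule(spec, matrix(0, 1, 5), grid, cfg2) - 0.693),
            0.011)
  # matches per-patient brute force over the grid for a p11-bearing matrix
  cfg3 <- utility_config(utility_matrix(0.5, 0.3))
  d <- generate_dataset(spec, 15, seed = 321)
  x <- dosewise:::covariate_matrix(d, 5)
  got <- oracle_rule(spec, x, grid, cfg3)
  for (i in 1:15) {
    j <- true_joint(spec, x[rep(i, length(grid)), , drop = FALSE], grid)
    u <- expected_utility(j, cfg3$matrix)
    expect_equal(got[i], grid[which.max(u)])
  }
  # under equal weights the copula correlation cancels from the decision
  spec0 <- spec; spec0$alpha <- 0
  expect_equal(oracle_rule(spec, x, grid, cfg2),
               oracle_rule(spec0, x, grid, cfg2))
})

test_that("fixed dosing is consistent for a dose-only truth", {
  spec0 <- scenario_spec("S0")
  d <- generate_dataset(spec0, 20000, seed = 331)
  cfg <- utility_config(utility_matrix(0.5, 0.5))
  fd <- fixed_dose_rule(d, dose_grid(), cfg)
  # the true dose-only utility 0.5 + 0.5 Phi(d) - 0.5 Phi(d - 1.386)
  # peaks at d = 0.693
  expect_lt(abs(fd$d_fix - 0.693), 0.1)
})

test_that("rule evaluation agrees with hand computation and dominance", {
  spec <- scenario_spec("S1")
  cfg <- utility_config(utility_matrix(0.3, 0.5))
  d <- generate_dataset(spec, 3, seed = 341)
  x <- dosewise:::covariate_matrix(d, 5)
  doses <- c(-0.5, 0, 0.7)
  ev <- evaluate_rule(spec, d, doses, cfg)
  j <- true_joint(spec, x, doses)
  expect_equal(ev$mean_dose, mean(doses))
  expect_equal(ev$sd_dose, sd(doses))
  expect_equal(ev$mean_E, mean(j$pE), tolerance = 1e-12)
  expect_equal(ev$mean_T, mean(j$pT), tolerance = 1e-12)
  expect_equal(ev$mean_utility, 100 * mean(expected_utility(j, cfg$matrix)),
               tolerance = 1e-12)
  # oracle dominates any other dose assignment patient by patient
  v <- generate_dataset(spec, 40, seed = 342)
  xv <- dosewise:::covariate_matrix(v, 5)
  grid <- dose_grid(n = 101L)
  d_opt <- oracle_rule(spec, xv, grid, cfg)
  u_opt <- expected_utility(true_joint(spec, xv, d_opt), cfg$matrix)
  for (alt in list(rep(0.3, 40), runif(40, -1, 1), -d_opt)) {
    alt <- pmin(pmax(alt, -1), 1)
    alt <- grid[vapply(alt, function(a) which.min(abs(grid - a)),
                       integer(1))]
    u_alt <- expected_utility(true_joint(spec, xv, alt), cfg$matrix)
    expect_true(all(u_opt >= u_alt - 1e-12))
  }
  # a constant rule has zero dose spread
  expect_equal(evaluate_rule(spec, v, rep(0.2, 40), cfg)$sd_dose, 0)
})

test_that("percent improvement anchors at the oracle and fixed dose", {
  expect_equal(pct_improvement(66.1, 58.7, 66.1), 100)
  expect_equal(pct_improvement(58.7, 58.7, 66.1), 0)
  expect_equal(pct_improvement(62.4, 58.7, 66.1), 50)
  expect_true(is.na(pct_improvement(60, 66.1, 66.1)))
  expect_equal(pct_improvement(c(66.1, 63.1, 58.7), 58.7, 66.1),
               c(100, 59.5, 0), tolerance = 0.001)
})

test_that("alternative scenario generators honour their laws", {
  d7 <- generate_dataset(scenario_spec("S7"), 300, seed = 351)
  expect_true(all(unlist(d7[, paste0("x", 1:5)]) %in% c(0, 1)))
  d3 <- generate_dataset(scenario_spec("S3"), 4000, seed = 352)
  expect_gt(cor(d3$x1, d3$x2), 0.3) # exchangeable block, attenuated by rejection
  d0 <- generate_dataset(scenario_spec("S0"), 200, seed = 353)
  expect_named(d0, c("id", "dose", "E", "T"))
  d4 <- generate_dataset(scenario_spec("S4"), 50, seed = 354)
  expect_equal(sum(grepl("^x", names(d4))), 20)
})

test_that("a short study run produces the full metrics table", {
  cfg <- study_config("S1", methods = c("M1", "M3", "M12"),
                      utilities = list(c(0.3, 0.5), c(0.5, 0.5)),
                      R = 2, n_train = 60, n_valid = 30,
                      grid = dose_grid(n = 21L), seed = 361,
                      rf_opts = list(num_trees = 60))
  res <- run_study(cfg)
  expect_setequal(names(res),
                  c("utility", "method", "mean_dose", "sd_dose", "mean_E",
                    "mean_T", "mean_utility", "pct_improvement", "n_reps",
                    "n_fail"))
  expect_equal(nrow(res), 6)
  expect_equal(res$n_fail, rep(0, 6))
  expect_equal(res$pct_improvement[res$method == "M1"], c(100, 100))
  expect_equal(res$pct_improvement[res$method == "M12"], c(0, 0))
  expect_equal(res$sd_dose[res$method == "M12"], c(0, 0))
  m3 <- res$pct_improvement[res$method == "M3"]
  expect_true(all(m3 <= 100 + 1e-9))
  # identical seed reproduces the metrics exactly
  res2 <- run_study(cfg)
  expect_equal(res, res2, ignore_attr = TRUE)
})
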