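test_that("utility matrix constructors validate and normalize", {
  m <- utility_matrix(0.3, 0.5)
  expect_equal(c(m$u00, m$u10, m$u01, m$u11), c(0.3, 1, 0, 0.5))
  expect_error(utility_matrix(0, 0.5), "strictly")
  expect_error(utility_matrix(0.5, 1), "strictly")
  # weighted-difference criterion pE - theta*pT maps to omega1 + omega2 = 1
  mt <- utility_matrix_theta(0.5)
  expect_equal(mt$omega1 + mt$omega2, 1)
  expect_equal(mt$omega1, 0.5 / 1.5)
})

test_that("expected utility matches both algebraic forms", {
  expect_equal(
    expected_utility(joint_prob(0.25, 0.25, 0.25, 0.25),
                     utility_matrix(0.3, 0.5)),
    0.45)
  j <- random_joints(200, seed = 11)
  for (om in list(c(0.3, 0.5), c(0.5, 0.5), c(0.7, 0.2))) {
    m <- utility_matrix(om[1], om[2])
    expanded <- m$omega1 + (1 - m$omega1) * j$pE - m$omega1 * j$pT +
      (m$omega1 + m$omega2 - 1) * j$p11
    expect_equal(expected_utility(j, m), expanded, tolerance = 1e-12)
  }
})

test_that("utility ignores p11 exactly when omega1 + omega2 = 1", {
  set.seed(21)
  m <- utility_matrix(0.4, 0.6)
  for (i in 1:50) {
    pE <- runif(1); pT <- runif(1)
    fb <- frechet_bounds(pE, pT)
    p11s <- runif(3, fb$lower, fb$upper)
    u <- vapply(p11s, function(p11) {
      expected_utility(joint_from_pE_pT_p11(pE, pT, p11), m)
    }, numeric(1))
    expect_equal(max(u) - min(u), 0, tolerance = 1e-12)
  }
  # and depends on it when omega1 + omega2 != 1
  m2 <- utility_matrix(0.5, 0.3)
  u2 <- expected_utility(joint_from_pE_pT_p11(0.6, 0.5, 0.3), m2)
  u3 <- expected_utility(joint_from_pE_pT_p11(0.6, 0.5, 0.2), m2)
  expect_equal(u2 - u3, -0.2 * 0.1, tolerance = 1e-12)
})

test_that("a published summary satisfies the omega = (0.5, 0.5) identity", {
  # with equal weights the utility reduces to 0.5 + 0.5 pE - 0.5 pT, so the
  # reported mean utility must recompute from mean E and mean T alone
  u <- 0.5 + 0.5 * 0.632 - 0.5 * 0.191
  expect_equal(u, 0.7205)
  expect_equal(100 * u, 72.1, tolerance = 0.051)
})

test_that("toxicity cap subtracts the penalty inclusively at the threshold", {
  cfg <- utility_config(utility_matrix(0.5, 0.5), rule = "tox_cap")
  at <- joint_from_pE_pT_p11(0.6, 0.3, 0.2)   # pT exactly at 0.3
  below <- joint_from_pE_pT_p11(0.6, 0.29, 0.2)
  expect_equal(utility_tox_cap(at, cfg),
               expected_utility(at, cfg$matrix) - 2 * 0.5 * 0.3)
  expect_equal(utility_tox_cap(below, cfg),
               expected_utility(below, cfg$matrix))
  # hand-evaluated case: pE=0.8, pT=0.4, p11=0.32, omega=(0.5,0.5)
  j <- joint_from_pE_pT_p11(0.8, 0.4, 0.32)
  expect_equal(expected_utility(j, cfg$matrix), 0.7, tolerance = 1e-12)
  expect_equal(utility_tox_cap(j, cfg), 0.3, tolerance = 1e-12)
})

test_that("dose penalty is quadratic around the fixed dose", {
  m <- utility_matrix(0.5, 0.5)
  cfg <- utility_config(m, rule = "dose_penalty", delta = 0.1, d_fix = 0.2)
  j <- joint_from_pE_pT_p11(0.7, 0.2, 0.1)
  expect_equal(utility_dose_penalty(j, 0.2, cfg), expected_utility(j, m))
  cfg0 <- utility_config(m, rule = "dose_penalty", delta = 0, d_fix = 0.2)
  expect_equal(utility_dose_penalty(j, -0.9, cfg0), expected_utility(j, m))
  # U = 0.6 at distance 1 with delta = 0.1 drops to 0.5
  j2 <- joint_from_pE_pT_p11(0.5, 0.3, 0.2) # utility 0.6
  expect_equal(expected_utility(j2, m), 0.6)
  expect_equal(utility_dose_penalty(j2, 1.2, cfg), 0.5, tolerance = 1e-12)
  cfg_bad <- utility_config(m, rule = "dose_penalty")
  expect_error(utility_dose_penalty(j, 0, cfg_bad), "d_fix")
})

test_that("pointwise dose selection matches brute force and breaks ties low", {
  grid <- dose_grid(n = 41L)
  m <- utility_matrix(0.4, 0.5)
  cfg <- utility_config(m)
  # constant utility -> lowest dose
  const <- joint_prob(rep(0.25, 41), 0.25, 0.25, 0.25, dose = grid)
  expect_equal(optimal_dose_pointwise(const, cfg)$dose, min(grid))
  # random curves vs exhaustive argmax
  set.seed(31)
  for (i in 1:25) {
    raw <- matrix(rexp(4 * 41), 41, 4); raw <- raw / rowSums(raw)
    curve <- joint_prob(raw[, 1], raw[, 2], raw[, 3], raw[, 4], dose = grid)
    u <- expected_utility(curve, m)
    expect_equal(optimal_dose_pointwise(curve, cfg)$dose,
                 grid[which(u == max(u))[1]])
  }
  # strictly increasing utility -> top dose
  inc <- joint_prob(rev(seq(0.3, 0.7, length.out = 41)), # p00 falls
                    seq(0.3, 0.7, length.out = 41), 0,
                    0, dose = grid)
  expect_equal(optimal_dose_pointwise(inc, cfg)$dose, max(grid))
  expect_error(optimal_dose_pointwise(const[0, ], cfg), "grid")
})

test_that("adding a constant to the utility matrix shifts utility, not argmax", {
  grid <- dose_grid(n = 21L)
  m <- utility_matrix(0.3, 0.5)
  m_shift <- m
  for (f in c("u00", "u10", "u01", "u11")) m_shift[[f]] <- m[[f]] + 0.25
  set.seed(41)
  raw <- matrix(rexp(4 * 21), 21, 4); raw <- raw / rowSums(raw)
  curve <- joint_prob(raw[, 1], raw[, 2], raw[, 3], raw[, 4], dose = grid)
  u0 <- expected_utility(curve, m)
  u1 <- expected_utility(curve, m_shift)
  expect_equal(u1, u0 + 0.25, tolerance = 1e-12)
  expect_equal(which.max(u1), which.max(u0))
})

test_that("oracle stationary point for the all-zero patient lands at 0.693", {
  # pE = Phi(d), pT = Phi(d - 1.386) with equal weights: the utility
  # derivative vanishes where phi(d) = phi(d - 1.386), i.e. d = 0.693
  grid <- dose_grid() # 201 points
  curve <- joint_from_marginals(pnorm(grid), pnorm(grid - 1.386),
                                copula_spec(0.8), dose = grid)
  cfg <- utility_config(utility_matrix(0.5, 0.5))
  got <- optimal_dose_pointwise(curve, cfg)$dose
  expect_lt(abs(got - 1.386 / 2), 0.011) # nearest grid point
})

test_that("posterior-mean rule reduces to pointwise for a degenerate posterior", {
  grid <- dose_grid(n = 11L)
  set.seed(51)
  raw <- matrix(rexp(4 * 11), 11, 4); raw <- raw / rowSums(raw)
  raw <- 0.6 * raw + 0.4 * 0.25 # keep cells away from the simplex boundary
  curve <- joint_prob(raw[, 1], raw[, 2], raw[, 3], raw[, 4], dose = grid)
  arr <- array(NA_real_, c(1, 11, 4))
  arr[1, , ] <- as.matrix(curve[, c("p00", "p10", "p01", "p11")])
  pd <- posterior_draws(arr, grid)
  cfg <- utility_config(utility_matrix(0.3, 0.5))
  expect_equal(optimal_dose_posterior_mean(pd, cfg)$dose,
               optimal_dose_pointwise(curve, cfg)$dose)
  # draws symmetric around a common mean curve give the mean-curve answer
  arr2 <- array(NA_real_, c(2, 11, 4))
  eps <- 0.05 * rep(c(1, -1), length.out = 11)
  base <- as.matrix(curve[, c("p00", "p10", "p01", "p11")])
  shift <- cbind(eps, -eps, 0, 0)
  arr2[1, , ] <- base + shift
  arr2[2, , ] <- base - shift
  pd2 <- posterior_draws(arr2, grid)
  expect_equal(optimal_dose_posterior_mean(pd2, cfg)$dose,
               optimal_dose_pointwise(curve, cfg)$dose)
})

test_that("posterior-probability rule uses strict dominance over d_fix", {
  grid <- c(-1, 0, 1)
  cfg <- utility_config(utility_matrix(0.5, 0.5), d_fix = 0)
  # identical draws with utility increasing in dose: every dose above
  # d_fix wins with probability 1, below with probability 0; argmax picks
  # the lowest dose with probability 1
  mk <- function(pE) cbind((1 - pE) * 0.8, pE * 0.8, (1 - pE) * 0.2,
                           pE * 0.2)
  arr <- array(NA_real_, c(3, 3, 4))
  for (s in 1:3) arr[s, , ] <- mk(c(0.2, 0.5, 0.8))
  pd <- posterior_draws(arr, grid)
  r <- optimal_dose_posterior_prob(pd, cfg)
  expect_equal(r$dose, 1)
  expect_equal(r$prob, 1)
  expect_equal(r$profile$prob, c(0, 0, 1))
  # all alternatives always below d_fix: probability 0 everywhere,
  # degenerate tie broken at the lowest grid dose
  for (s in 1:3) arr[s, , ] <- mk(c(0.2, 0.8, 0.5))
  pd <- posterior_draws(arr, grid)
  r <- optimal_dose_posterior_prob(pd, cfg)
  expect_equal(r$dose, -1)
  expect_equal(r$prob, 0)
  # 50/50 split at one dose vs certain win at another
  arr2 <- array(NA_real_, c(2, 3, 4))
  arr2[1, , ] <- mk(c(0.9, 0.5, 0.8))
  arr2[2, , ] <- mk(c(0.1, 0.5, 0.8))
  pd2 <- posterior_draws(arr2, grid)
  expect_equal(optimal_dose_posterior_prob(pd2, cfg)$dose, 1)
})

test_that("posterior containers validate shapes", {
  arr <- array(0.25, c(2, 5, 4))
  expect_error(posterior_draws(arr, 1:4), "grid")
  bad <- arr; bad[1, 1, 1] <- 0.5
  expect_error(posterior_draws(bad, seq(-1, 1, length.out = 5)), "valid")
  pd <- posterior_draws(arr, seq(-1, 1, length.out = 5))
  u <- posterior_utility(pd, utility_config(utility_matrix(0.3, 0.5)))
  expect_equal(dim(u), c(2, 5))
  expect_equal(u[1, 1], 0.45)
})
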