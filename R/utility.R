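# Utility matrices, utility functions and dose-selection rules.
#
# Internally utilities live on the [0, 1] scale; study-level reports multiply
# by 100. Argmax ties are always broken by the lowest dose (clinically
# conservative).

#' Utility matrix for bivariate binary efficacy/toxicity outcomes
#'
#' The canonical two-parameter matrix assigns utility 1 to (E=1, T=0),
#' 0 to (E=0, T=1), `omega1` to (E=0, T=0) and `omega2` to (E=1, T=1),
#' with `0 < omega1 < 1` and `0 < omega2 < 1`. When `omega1 + omega2 = 1`
#' the expected utility depends on the joint distribution only through the
#' marginals; otherwise the probability of (E=1, T=1) enters with weight
#' `omega1 + omega2 - 1`.
#'
#' @param omega1 Utility of the (E=0, T=0) outcome, in (0, 1).
#' @param omega2 Utility of the (E=1, T=1) outcome, in (0, 1).
#' @return An object of class `utility_matrix` with elements `u00`, `u10`,
#'   `u01`, `u11`, `omega1`, `omega2`.
#' @seealso [utility_matrix_theta()] for the single-parameter trade-off form.
#' @examples
#' utility_matrix(0.3, 0.5)
#' @export
utility_matrix <- function(omega1, omega2) {
  stopifnot(is.numeric(omega1), is.numeric(omega2),
            length(omega1) == 1L, length(omega2) == 1L)
  if (omega1 <= 0 || omega1 >= 1 || omega2 <= 0 || omega2 >= 1) {
    stop("omega1 and omega2 must lie strictly in (0, 1)")
  }
  structure(
    list(u00 = omega1, u10 = 1, u01 = 0, u11 = omega2,
         omega1 = omega1, omega2 = omega2),
    class = "utility_matrix"
  )
}

#' Utility matrix from a single efficacy/toxicity trade-off parameter
#'
#' The weighted-difference criterion `pE - theta * pT` corresponds to the
#' matrix (u00, u10, u01, u11) = (0, 1, -theta, 1 - theta). Expected utility
#' is invariant (up to a positive affine transform, which never changes the
#' argmax) to rescaling the matrix onto the [0, 1] range, giving
#' `omega1 = theta / (1 + theta)` and `omega2 = 1 / (1 + theta)`, which
#' satisfy `omega1 + omega2 = 1`.
#'
#' @param theta Positive trade-off weight on the toxicity probability.
#' @return A `utility_matrix`.
#' @export
utility_matrix_theta <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  utility_matrix(theta / (1 + theta), 1 / (1 + theta))
}

#' @export
print.utility_matrix <- function(x, ...) {
  cat("Utility matrix (omega1 =", x$omega1, ", omega2 =", x$omega2, ")\n")
  m <- matrix(c(x$u00, x$u01, x$u10, x$u11), 2, 2,
              dimnames = list(c("T=0", "T=1"), c("E=0", "E=1")))
  print(m)
  invisible(x)
}

#' Joint outcome probabilities
#'
#' Container for the four cell probabilities of the bivariate binary
#' (efficacy, toxicity) outcome, one row per evaluation point (for example
#' one row per dose on a grid). All constructors validate that cells are
#' nonnegative and sum to one.
#'
#' @param p00,p10,p01,p11 Numeric vectors of cell probabilities
#'   (`pET` with E the first index), recycled to a common length.
#' @param dose Optional numeric vector of doses attached as a column.
#' @param tol Tolerance for the sum-to-one check.
#' @return A `data.frame` of class `joint_prob` with columns `p00`, `p10`,
#'   `p01`, `p11` (and `dose` if supplied), plus derived marginals
#'   `pE = p10 + p11` and `pT = p01 + p11`.
#' @examples
#' joint_prob(0.25, 0.25, 0.25, 0.25)
#' @export
joint_prob <- function(p00, p10, p01, p11, dose = NULL, tol = 1e-9) {
  n <- max(length(p00), length(p10), length(p01), length(p11))
  df <- data.frame(p00 = rep_len(p00, n), p10 = rep_len(p10, n),
                   p01 = rep_len(p01, n), p11 = rep_len(p11, n))
  cells <- as.matrix(df)
  if (any(!is.finite(cells))) stop("joint_prob: non-finite cell probability")
  if (any(cells < -tol) || any(cells > 1 + tol)) {
    stop("joint_prob: cell probabilities must lie in [0, 1]")
  }
  s <- rowSums(cells)
  if (any(abs(s - 1) > tol)) {
    stop("joint_prob: cell probabilities must sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  }
  df$pE <- df$p10 + df$p11
  df$pT <- df$p01 + df$p11
  if (!is.null(dose)) {
    stopifnot(length(dose) == n)
    df$dose <- dose
  }
  class(df) <- c("joint_prob", "data.frame")
  df
}

#' Dose grid
#'
#' Equally spaced candidate doses. The default mirrors the standardized dose
#' range \eqn{[-1, 1]} with 201 points (step 0.01); resolution is a package
#' choice, configurable here.
#'
#' @param d_min,d_max Range endpoints.
#' @param n Number of grid points (at least 2).
#' @return Strictly increasing numeric vector.
#' @export
dose_grid <- function(d_min = -1, d_max = 1, n = 201L) {
  stopifnot(n >= 2, d_max > d_min)
  seq(d_min, d_max, length.out = n)
}

#' Configuration of the utility criterion and selection rule
#'
#' @param matrix A [utility_matrix()].
#' @param rule One of `"base"` (plain expected utility), `"tox_cap"`
#'   (extra toxicity penalty once the toxicity probability reaches
#'   `tox_threshold`) or `"dose_penalty"` (quadratic penalty on distance
#'   from a population fixed dose).
#' @param tox_threshold Toxicity probability at and above which the extra
#'   penalty applies (inclusive indicator); default 0.3.
#' @param tox_multiplier Multiplier `c` in the penalty
#'   `c * omega1 * pT`; the default 2 triples the effective toxicity weight
#'   above the threshold.
#' @param delta Nonnegative weight of the quadratic dose penalty
#'   `delta * (d - d_fix)^2`; default 0.1.
#' @param d_fix Population fixed dose used by the dose-penalty utility and
#'   by the posterior-probability selection rule.
#' @return An object of class `utility_config`.
#' @export
utility_config <- function(matrix, rule = c("base", "tox_cap", "dose_penalty"),
                           tox_threshold = 0.3, tox_multiplier = 2,
                           delta = 0.1, d_fix = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(matrix, "utility_matrix"))
  if (tox_threshold <= 0 || tox_threshold >= 1) {
    stop("tox_threshold must lie in (0, 1)")
  }
  if (delta < 0) stop("delta must be nonnegative")
  if (tox_multiplier <= 0) stop("tox_multiplier must be positive")
  structure(
    list(matrix = matrix, rule = rule, tox_threshold = tox_threshold,
         tox_multiplier = tox_multiplier, delta = delta, d_fix = d_fix),
    class = "utility_config"
  )
}

#' Expected utility of a joint outcome distribution
#'
#' The expectation of the utility matrix under the joint distribution:
#' `omega1 * p00 + p10 + omega2 * p11`, equivalently
#' `omega1 + (1 - omega1) * pE - omega1 * pT + (omega1 + omega2 - 1) * p11`.
#'
#' @param joint A [joint_prob()] (one row per evaluation point).
#' @param m A [utility_matrix()].
#' @return Numeric vector of utilities on the [0, 1] scale.
#' @examples
#' expected_utility(joint_prob(0.25, 0.25, 0.25, 0.25), utility_matrix(0.3, 0.5))
#' @export
expected_utility <- function(joint, m) {
  stopifnot(inherits(joint, "joint_prob"), inherits(m, "utility_matrix"))
  m$u00 * joint$p00 + m$u10 * joint$p10 + m$u01 * joint$p01 + m$u11 * joint$p11
}

# matrix-core version used by the vectorized simulation paths:
# pE, pT, p11 conformable arrays -> utility array
utility_from_marginals <- function(pE, pT, p11, m) {
  m$omega1 + (1 - m$omega1) * pE - m$omega1 * pT +
    (m$omega1 + m$omega2 - 1) * p11
}

#' Toxicity-capped utility
#'
#' Subtracts `tox_multiplier * omega1 * pT` from the expected utility
#' whenever the toxicity probability reaches the threshold (inclusive
#' indicator), discouraging doses with clinically unacceptable toxicity
#' regardless of efficacy.
#'
#' @inheritParams expected_utility
#' @param cfg A [utility_config()] with `rule = "tox_cap"`.
#' @return Numeric vector of penalized utilities.
#' @export
utility_tox_cap <- function(joint, cfg) {
  stopifnot(inherits(cfg, "utility_config"))
  if (cfg$rule != "tox_cap") stop("cfg$rule must be 'tox_cap'")
  u <- expected_utility(joint, cfg$matrix)
  pT <- joint$pT
  u - cfg$tox_multiplier * cfg$matrix$omega1 * pT * (pT >= cfg$tox_threshold)
}

#' Dose-penalized utility
#'
#' Subtracts `delta * (d - d_fix)^2` from the expected utility, shrinking
#' individualized doses toward a population fixed dose and limiting
#' between-patient dose variability.
#'
#' @inheritParams expected_utility
#' @param d Numeric vector of doses at which the joint rows are evaluated.
#' @param cfg A [utility_config()] with `rule = "dose_penalty"` and `d_fix`
#'   set.
#' @return Numeric vector of penalized utilities.
#' @export
utility_dose_penalty <- function(joint, d, cfg) {
  stopifnot(inherits(cfg, "utility_config"))
  if (cfg$rule != "dose_penalty") stop("cfg$rule must be 'dose_penalty'")
  if (is.null(cfg$d_fix)) stop("dose-penalty utility requires cfg$d_fix")
  expected_utility(joint, cfg$matrix) - cfg$delta * (d - cfg$d_fix)^2
}

# Evaluate the configured utility for a joint curve over doses d.
utility_by_rule <- function(joint, d, cfg) {
  switch(cfg$rule,
    base = expected_utility(joint, cfg$matrix),
    tox_cap = utility_tox_cap(joint, cfg),
    dose_penalty = utility_dose_penalty(joint, d, cfg)
  )
}

#' Pointwise optimal dose from a joint-probability curve
#'
#' Maximizes the configured utility over the dose grid; ties are broken by
#' the lowest dose.
#'
#' @param curve A [joint_prob()] with one row per grid point.
#' @param grid Dose grid matching the rows of `curve` (taken from
#'   `curve$dose` when omitted).
#' @param cfg A [utility_config()].
#' @return List with elements `dose` (the maximizer), `utility` (its
#'   utility) and `profile` (`data.frame` of dose and utility).
#' @export
optimal_dose_pointwise <- function(curve, cfg, grid = NULL) {
  stopifnot(inherits(curve, "joint_prob"))
  if (is.null(grid)) grid <- curve$dose
  if (is.null(grid) || length(grid) == 0L) stop("empty dose grid")
  if (length(grid) != nrow(curve)) {
    stop("grid length must match the number of joint-probability rows")
  }
  u <- utility_by_rule(curve, grid, cfg)
  i <- which.max(u) # first max = lowest dose on an increasing grid
  list(dose = grid[i], utility = u[i],
       profile = data.frame(dose = grid, utility = u))
}

#' Posterior draws of joint probabilities over a dose grid
#'
#' @param draws Numeric array `S x D x 4` (posterior draws by grid doses by
#'   joint cells in the order `p00, p10, p01, p11`).
#' @param grid Dose grid of length `D`.
#' @param alpha Optional per-draw copula correlations (length `S`).
#' @param tol Validation tolerance for cell sums.
#' @return Object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, grid, alpha = NULL, tol = 1e-6) {
  stopifnot(is.array(draws), length(dim(draws)) == 3L, dim(draws)[3] == 4L)
  if (dim(draws)[2] != length(grid)) {
    stop("grid length must equal the second dimension of draws")
  }
  if (dim(draws)[1] < 1L) stop("at least one posterior draw is required")
  s <- draws[, , 1] + draws[, , 2] + draws[, , 3] + draws[, , 4]
  if (any(abs(s - 1) > tol) || any(draws < -tol)) {
    stop("posterior draws must be valid joint probabilities")
  }
  dimnames(draws)[[3]] <- c("p00", "p10", "p01", "p11")
  structure(list(draws = draws, grid = as.numeric(grid), alpha = alpha),
            class = "posterior_draws")
}

#' Per-draw utility profiles
#'
#' Applies the configured utility to every posterior draw of the joint
#' probabilities, giving the posterior distribution of the utility at each
#' grid dose.
#'
#' @param pd A [posterior_draws()] object.
#' @param cfg A [utility_config()].
#' @return `S x D` matrix of utilities.
#' @export
posterior_utility <- function(pd, cfg) {
  stopifnot(inherits(pd, "posterior_draws"))
  a <- pd$draws
  pE <- a[, , "p10"] + a[, , "p11"]
  pT <- a[, , "p01"] + a[, , "p11"]
  m <- cfg$matrix
  u <- utility_from_marginals(pE, pT, a[, , "p11"], m)
  u <- matrix(u, dim(a)[1], dim(a)[2])
  if (cfg$rule == "tox_cap") {
    u <- u - cfg$tox_multiplier * m$omega1 * pT * (pT >= cfg$tox_threshold)
  } else if (cfg$rule == "dose_penalty") {
    if (is.null(cfg$d_fix)) stop("dose-penalty utility requires cfg$d_fix")
    u <- u - rep(cfg$delta * (pd$grid - cfg$d_fix)^2, each = dim(a)[1])
  }
  u
}

#' Optimal dose by the posterior-mean rule
#'
#' Selects the grid dose maximizing the across-draw mean of the utility
#' (the posterior expected utility); ties go to the lowest dose.
#'
#' @inheritParams posterior_utility
#' @return List with `dose`, `utility` (posterior-mean utility at the
#'   selected dose) and `profile` (posterior-mean utility by dose).
#' @export
optimal_dose_posterior_mean <- function(pd, cfg) {
  u <- posterior_utility(pd, cfg)
  mu <- colMeans(u)
  i <- which.max(mu)
  list(dose = pd$grid[i], utility = mu[i],
       profile = data.frame(dose = pd$grid, utility = mu))
}

#' Optimal dose by the posterior-probability rule
#'
#' Selects the grid dose maximizing the posterior probability that its
#' utility strictly exceeds the utility at a fixed reference dose. At the
#' reference dose itself the strict comparison makes the probability 0.
#' Doses whose expected-utility gains are small relative to their posterior
#' uncertainty are thereby avoided. Ties go to the lowest dose.
#'
#' @inheritParams posterior_utility
#' @param d_fix Reference dose; defaults to `cfg$d_fix`. Snapped to the
#'   nearest grid point (with a message) if off-grid.
#' @return List with `dose`, `prob` (winning posterior probability) and
#'   `profile` (probability by dose).
#' @export
optimal_dose_posterior_prob <- function(pd, cfg, d_fix = cfg$d_fix) {
  if (is.null(d_fix)) stop("posterior-probability rule requires d_fix")
  u <- posterior_utility(pd, cfg)
  j <- which.min(abs(pd$grid - d_fix))
  if (abs(pd$grid[j] - d_fix) > 1e-8) {
    message("d_fix = ", format(d_fix), " snapped to grid dose ",
            format(pd$grid[j]))
  }
  pr <- colMeans(u > u[, j])
  i <- which.max(pr)
  list(dose = pd$grid[i], prob = pr[i],
       profile = data.frame(dose = pd$grid, prob = pr))
}
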