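# Isotonic (nondecreasing-in-dose) adjustment of estimated probability
# curves: weighted PAVA for the marginals, then per-dose adjustment of the
# joint cells within the Frechet bounds implied by the monotonized
# marginals.

#' Pool-adjacent-violators projection onto nondecreasing sequences
#'
#' Weighted least-squares isotonic regression: returns the nondecreasing
#' sequence minimizing `sum(w * (x - fit)^2)` by pooling adjacent
#' violating blocks into their weighted means.
#'
#' @param values Numeric vector.
#' @param weights Positive weights of the same length (default: unit
#'   weights, which is how dose-curves are monotonized here).
#' @return Nondecreasing numeric vector of the same length.
#' @examples
#' pava_nondecreasing(c(1, 0.5, 0.8)) # c(0.75, 0.75, 0.8)
#' @export
pava_nondecreasing <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  if (n == 0L) stop("pava_nondecreasing: empty input")
  stopifnot(length(weights) == n, all(weights > 0), all(is.finite(values)))
  # stack of blocks: running (mean, weight, size)
  mean_ <- numeric(n); w_ <- numeric(n); len_ <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    mean_[top] <- values[i]; w_[top] <- weights[i]; len_[top] <- 1L
    while (top > 1L && mean_[top - 1L] > mean_[top]) {
      wsum <- w_[top - 1L] + w_[top]
      mean_[top - 1L] <- (w_[top - 1L] * mean_[top - 1L] +
                          w_[top] * mean_[top]) / wsum
      w_[top - 1L] <- wsum
      len_[top - 1L] <- len_[top - 1L] + len_[top]
      top <- top - 1L
    }
  }
  rep(mean_[seq_len(top)], len_[seq_len(top)])
}

#' Monotonize a joint-probability dose-curve
#'
#' Projects the marginal efficacy and toxicity curves onto nondecreasing
#' sequences with [pava_nondecreasing()], then re-derives joint cells
#' consistent with the monotonized marginals. At each dose the adjusted
#' `p11*` must lie in the Frechet interval
#' `[max(0, pE* + pT* - 1), min(pE*, pT*)]`:
#'
#' * `variant = "p11_only"` minimizes `|p11* - p11|`, i.e. clips the
#'   estimated `p11` to the interval;
#' * `variant = "total_deviation"` minimizes the L1 distance over all four
#'   cells, `|p11* - p11| + |p10* - p10| + |p01* - p01| + |p00* - p00|`.
#'   With the other cells determined by `p11*` and the monotone marginals,
#'   the objective is piecewise linear in `p11*`, so it is minimized
#'   exactly by evaluating the interval endpoints and the four kink points
#'   (clipped into the interval); ties go to the smallest `p11*`.
#'
#' The remaining cells follow sequentially: `p10* = pE* - p11*`,
#' `p01* = pT* - p11*`, `p00* = 1 - pE* - pT* + p11*`. Cells are floored
#' at 0 when floating error pushes them below `-1e-12`.
#'
#' @param curve A [joint_prob()] curve over an increasing dose grid (one
#'   row per dose).
#' @param variant `"p11_only"` or `"total_deviation"`.
#' @return Object of class `adjusted_joint_curve`: a list with `original`
#'   (the input), `adjusted` (a [joint_prob()] with the same doses) and
#'   `variant`.
#' @export
adjust_joint_p11 <- function(curve, variant = c("p11_only", "total_deviation")) {
  variant <- match.arg(variant)
  stopifnot(inherits(curve, "joint_prob"))
  pE_star <- pava_nondecreasing(curve$pE)
  pT_star <- pava_nondecreasing(curve$pT)
  fb <- frechet_bounds(pmin(pmax(pE_star, 0), 1), pmin(pmax(pT_star, 0), 1))
  lo <- fb$lower; hi <- fb$upper
  n <- nrow(curve)
  p11_star <- numeric(n)
  if (variant == "p11_only") {
    p11_star <- pmin(pmax(curve$p11, lo), hi)
  } else {
    for (i in seq_len(n)) {
      kinks <- c(curve$p11[i],
                 pE_star[i] - curve$p10[i],
                 pT_star[i] - curve$p01[i],
                 curve$p00[i] - (1 - pE_star[i] - pT_star[i]))
      cand <- sort(unique(c(lo[i], hi[i], pmin(pmax(kinks, lo[i]), hi[i]))))
      obj <- abs(cand - curve$p11[i]) +
        abs((pE_star[i] - cand) - curve$p10[i]) +
        abs((pT_star[i] - cand) - curve$p01[i]) +
        abs((1 - pE_star[i] - pT_star[i] + cand) - curve$p00[i])
      p11_star[i] <- cand[which.min(obj)] # first min = smallest p11*
    }
  }
  p10_star <- pE_star - p11_star
  p01_star <- pT_star - p11_star
  p00_star <- 1 - pE_star - pT_star + p11_star
  fix0 <- function(p) {
    if (any(p < -1e-12)) stop("adjusted cell fell below -1e-12")
    pmax(p, 0)
  }
  adj <- joint_prob(fix0(p00_star), fix0(p10_star), fix0(p01_star),
                    fix0(p11_star), dose = curve$dose, tol = 1e-8)
  structure(list(original = curve, adjusted = adj, variant = variant),
            class = "adjusted_joint_curve")
}
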