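# Shared fixtures and independent brute-force oracles used across tests.

# random valid joint distributions (rows of a joint_prob)
random_joints <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw <- matrix(rexp(4 * n), n, 4)
  raw <- raw / rowSums(raw)
  joint_prob(raw[, 1], raw[, 2], raw[, 3], raw[, 4])
}

# a joint with given marginals and p11 (must satisfy Frechet feasibility)
joint_from_pE_pT_p11 <- function(pE, pT, p11) {
  joint_prob(1 - pE - pT + p11, pE - p11, pT - p11, p11)
}

# exact weighted isotonic least squares by enumeration of consecutive-block
# partitions (2^(n-1) partitions; exact for small n)
pava_bruteforce <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    fit <- numeric(n)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      i <- starts[b]:ends[b]
      means[b] <- sum(weights[i] * values[i]) / sum(weights[i])
      fit[i] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(weights * (values - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# small scenario-1 dataset cached per session to keep model tests fast
scenario1_data <- local({
  cache <- NULL
  function(n = 200, seed = 1234) {
    if (is.null(cache)) {
      cache <<- generate_dataset(scenario_spec("S1"), n, seed = seed)
    }
    cache
  }
})
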