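# Gaussian-copula construction of the joint (E, T) distribution from probit
# marginals, pseudo-likelihood estimation of the copula correlation, and
# Frechet feasibility bounds.

PROB_EPS <- 1e-10   # clipping for marginal probabilities entering qnorm
CELL_FLOOR <- 1e-12 # floor for joint cells inside log-likelihoods
ALPHA_CAP <- 0.99   # numerical cap on |alpha|

#' Copula specification
#'
#' @param alpha Correlation of the underlying bivariate normal,
#'   `|alpha| <= 0.99` (values beyond the cap error). Ignored under
#'   independence.
#' @param mode `"copula"` or `"independence"`.
#' @return Object of class `copula_spec`.
#' @export
copula_spec <- function(alpha = 0, mode = c("copula", "independence")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (mode == "copula" && abs(alpha) > ALPHA_CAP) {
    stop("|alpha| must be <= ", ALPHA_CAP)
  }
  structure(list(alpha = alpha, mode = mode), class = "copula_spec")
}

#' Joint outcome distribution from marginal probabilities
#'
#' Links the marginal efficacy and toxicity probabilities into a joint
#' distribution through a Gaussian copula:
#' `p00 = Phi2(qnorm(1 - pE), qnorm(1 - pT) | alpha)`, with the remaining
#' cells from complement algebra (`p10 = (1 - pT) - p00`,
#' `p01 = (1 - pE) - p00`, `p11 = pE + pT - 1 + p00`), so the input
#' marginals are reproduced exactly. Under independence `p00` is the
#' product of the complements.
#'
#' @param pE,pT Marginal probabilities of efficacy and toxicity (vectors,
#'   recycled). Values at the boundary are clipped to
#'   `[1e-10, 1 - 1e-10]`.
#' @param spec A [copula_spec()].
#' @param dose Optional dose column passed through to the result.
#' @return A [joint_prob()].
#' @examples
#' joint_from_marginals(0.3, 0.6, copula_spec(0))     # p00 = 0.7 * 0.4
#' joint_from_marginals(0.5, 0.5, copula_spec(0.8))   # p00 ~ 0.3976
#' @export
joint_from_marginals <- function(pE, pT, spec = copula_spec(0), dose = NULL) {
  stopifnot(inherits(spec, "copula_spec"))
  n <- max(length(pE), length(pT))
  pE <- pmin(pmax(rep_len(pE, n), PROB_EPS), 1 - PROB_EPS)
  pT <- pmin(pmax(rep_len(pT, n), PROB_EPS), 1 - PROB_EPS)
  p00 <- if (spec$mode == "independence" || spec$alpha == 0) {
    (1 - pE) * (1 - pT)
  } else {
    pbvnorm(qnorm(1 - pE), qnorm(1 - pT), spec$alpha)
  }
  # keep cells inside the Frechet box despite floating error
  p00 <- pmin(pmax(p00, pmax(0, 1 - pE - pT)), pmin(1 - pE, 1 - pT))
  joint_prob(p00, (1 - pT) - p00, (1 - pE) - p00, pE + pT - 1 + p00,
             dose = dose)
}

#' Frechet bounds for the probability of both outcomes
#'
#' Feasible range of `p11 = P(E=1, T=1)` given the marginals:
#' `[max(0, pE + pT - 1), min(pE, pT)]`.
#'
#' @param pE,pT Marginal probabilities (vectors, recycled).
#' @return List with numeric vectors `lower` and `upper`.
#' @export
frechet_bounds <- function(pE, pT) {
  n <- max(length(pE), length(pT))
  pE <- rep_len(pE, n)
  pT <- rep_len(pT, n)
  stopifnot(all(pE >= 0 & pE <= 1), all(pT >= 0 & pT <= 1))
  list(lower = pmax(0, pE + pT - 1), upper = pmin(pE, pT))
}

#' Copula pseudo-log-likelihood
#'
#' Log-likelihood of the observed bivariate binary outcomes under the
#' Gaussian copula with the (already estimated) marginal probabilities
#' plugged in: each record contributes the log of the joint cell selected
#' by its `(E, T)` value. Cells are floored at `1e-12` before logging.
#'
#' @param E,T Binary outcome vectors (0/1).
#' @param pE,pT Fitted marginal probabilities for each record.
#' @param alpha Copula correlation.
#' @return Scalar log-likelihood.
#' @export
copula_loglik <- function(E, T, pE, pT, alpha) {
  stopifnot(length(E) == length(T), length(E) == length(pE),
            length(E) == length(pT), all(E %in% c(0, 1)), all(T %in% c(0, 1)))
  j <- joint_from_marginals(pE, pT, copula_spec(alpha))
  cell <- ifelse(E == 0,
                 ifelse(T == 0, j$p00, j$p01),
                 ifelse(T == 0, j$p10, j$p11))
  sum(log(pmax(cell, CELL_FLOOR)))
}

#' Two-stage pseudo-likelihood estimate of the copula correlation
#'
#' With marginal probabilities fitted first (for tree ensembles,
#' out-of-bag/out-of-fold predictions at the observed doses), the single
#' copula parameter is estimated by one-dimensional maximization of
#' [copula_loglik()] over `[-0.99, 0.99]` (golden-section search via
#' [stats::optimize()]).
#'
#' @inheritParams copula_loglik
#' @param tol Convergence tolerance of the search.
#' @return Scalar `alpha_hat`.
#' @export
estimate_alpha <- function(E, T, pE, pT, tol = 1e-4) {
  if (length(E) < 2L) stop("need at least 2 records to estimate alpha")
  f <- function(a) copula_loglik(E, T, pE, pT, a)
  opt <- optimize(f, interval = c(-ALPHA_CAP, ALPHA_CAP),
                  maximum = TRUE, tol = tol)
  if (!is.finite(opt$objective)) stop("copula likelihood is non-finite")
  # optimize() can stop short of a boundary maximum; check the endpoints
  ends <- c(-ALPHA_CAP, ALPHA_CAP)
  le <- vapply(ends, f, numeric(1))
  if (max(le) > opt$objective) {
    return(ends[which.max(le)])
  }
  opt$maximum
}
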