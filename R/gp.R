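# Bayesian Gaussian-process probit models for the bivariate binary outcome.
#
# Latent functions fE ~ N(0, KE), fT ~ N(0, KT) with ARD Gaussian kernels;
# probit marginals Pr(E=0) = Phi(fE + a), Pr(T=0) = Phi(fT + b); the
# four-cell multinomial likelihood combines them under independence or a
# Gaussian copula. Inverse length-scales rho_q get a horseshoe prior
# (rho_q ~ N(0, lambda_q^2 tau^2), lambda_q, tau ~ half-Cauchy(0,1), one
# set per outcome); signal magnitudes half-normal(0,1); intercepts
# standard normal.
#
# Posterior sampling is Metropolis-within-Gibbs: elliptical slice sampling
# for the whitened latents (f = L u, u ~ N(0, I), so kernel updates leave
# the latent prior invariant) and adaptive random-walk Metropolis for the
# hyperparameter blocks. Gradient-based samplers are unnecessary at the
# dense-kernel sample sizes this model targets (n up to a few hundred).

#' ARD (automatic relevance determination) Gaussian kernel
#'
#' `k(zi, zj) = eta^2 * exp(-0.5 * sum_q rho_q^2 * (zi_q - zj_q)^2)`.
#' `rho_q` multiplies the squared distance (an inverse length-scale):
#' a `rho_q` near zero makes the covariance independent of input `q`,
#' effectively removing it from the inference.
#'
#' @param zi,zj Numeric input vectors of equal length.
#' @param eta Signal magnitude (`eta^2` is the signal variance).
#' @param rho Vector of per-dimension ARD weights.
#' @return Covariance scalar.
#' @examples
#' ard_kernel(c(0, 0), c(0, 0), eta = 2, rho = c(1, 1)) # eta^2
#' ard_kernel(0, 1, eta = 1, rho = 1)                   # exp(-0.5)
#' @export
ard_kernel <- function(zi, zj, eta, rho) {
  if (length(zi) != length(zj)) stop("ard_kernel: dimension mismatch")
  stopifnot(length(rho) == length(zi), eta > 0)
  eta^2 * exp(-0.5 * sum(rho^2 * (zi - zj)^2))
}

# per-dimension squared-distance matrices between rows of Z1 and Z2
sqdist_by_dim <- function(Z1, Z2) {
  lapply(seq_len(ncol(Z1)), function(q) outer(Z1[, q], Z2[, q], "-")^2)
}

kernel_from_dists <- function(dists, eta, rho) {
  M <- 0
  for (q in seq_along(dists)) M <- M + rho[q]^2 * dists[[q]]
  eta^2 * exp(-0.5 * M)
}

chol_jitter <- function(K, jitter = 1e-6, max_jitter = 1e-4) {
  j <- jitter
  repeat {
    L <- tryCatch(t(chol(K + diag(j, nrow(K)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    j <- j * 10
    if (j > max_jitter) stop("kernel matrix not positive definite at jitter ",
                             max_jitter)
  }
}

# four joint cells from latent probit indices; rows of cbind output are
# (p00, p10, p01, p11); hE = fE + a, hT = fT + b
gp_cells <- function(hE, hT, mode, alpha) {
  PhiE0 <- pnorm(hE) # Pr(E=0)
  PhiT0 <- pnorm(hT)
  p00 <- if (mode == "independence") PhiE0 * PhiT0 else {
    pbvnorm(hE, hT, alpha)
  }
  p00 <- pmin(pmax(p00, pmax(0, PhiE0 + PhiT0 - 1)), pmin(PhiE0, PhiT0))
  cbind(p00 = p00, p10 = PhiT0 - p00, p01 = PhiE0 - p00,
        p11 = 1 - PhiE0 - PhiT0 + p00)
}

gp_loglik <- function(fE, fT, a, b, mode, alpha, ycell) {
  cells <- gp_cells(fE + a, fT + b, mode, alpha)
  sum(log(pmax(cells[cbind(seq_along(ycell), ycell)], 1e-12)))
}

# log prior pieces for one outcome's hyperparameters, on the sampling
# scale (log eta, rho, log lambda, log tau); Jacobians of the log
# transforms included. The probit intercept is updated with the whitened
# latents (standard-normal prior), not here.
lp_half_cauchy <- function(x, lx) sum(log(2 / pi) - log1p(x^2) + lx)

# kernel block: signal magnitude (half-normal) and ARD weights given their
# horseshoe scales
gp_kernel_lp <- function(h) {
  eta <- exp(h$leta)
  (log(2) + dnorm(eta, log = TRUE) + h$leta) +
    sum(dnorm(h$rho, 0, exp(h$llam) * exp(h$ltau), log = TRUE))
}

# horseshoe-scale block: conditional of (lambda, tau) given rho needs no
# likelihood evaluation
gp_scales_lp <- function(h) {
  lam <- exp(h$llam); tau <- exp(h$ltau)
  sum(dnorm(h$rho, 0, lam * tau, log = TRUE)) +
    lp_half_cauchy(lam, h$llam) + lp_half_cauchy(tau, h$ltau)
}

hyp_pack <- function(h) c(h$leta, h$rho, h$llam, h$ltau)
hyp_unpack <- function(v, p) {
  list(leta = v[1], rho = v[2:(p + 1)], llam = v[(p + 2):(2 * p + 1)],
       ltau = v[2 * p + 2])
}

# elliptical slice sampling step for whitened latents
ess_step <- function(u, ll_fun, ll_cur) {
  v <- rnorm(length(u))
  logy <- ll_cur + log(runif(1))
  theta <- runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi; hi <- theta
  repeat {
    prop <- u * cos(theta) + v * sin(theta)
    ll <- ll_fun(prop)
    if (ll > logy) return(list(u = prop, ll = ll))
    if (theta < 0) lo <- theta else hi <- theta
    if (hi - lo < 1e-12) return(list(u = u, ll = ll_cur))
    theta <- runif(1, lo, hi)
  }
}

#' Fit the Gaussian-process probit model
#'
#' @param data Patient table with covariates `x1..xQ`, `dose`, `E`, `T`.
#' @param mode `"independence"` (default; the joint is the product of the
#'   probit marginals) or `"copula"` (Gaussian copula with correlation
#'   sampled alongside the other parameters).
#' @param chains,warmup,iter MCMC configuration: number of chains, warmup
#'   iterations, and retained post-warmup iterations per chain.
#' @param jitter Diagonal jitter added to kernel matrices (escalated to
#'   at most 1e-4 if a Cholesky fails).
#' @param seed Integer seed.
#' @param verbose Print progress.
#' @return Object of class `gp_fit` containing posterior draws of the
#'   latent vectors and hyperparameters, the standardization statistics,
#'   and a diagnostics table (split-chain R-hat and effective sample size
#'   for key scalar parameters).
#' @export
fit_gp <- function(data, mode = c("independence", "copula"), chains = 2L,
                   warmup = 500L, iter = 500L, jitter = 1e-6, seed = NULL,
                   verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("dose", "E", "T") %in% names(data)))
  n <- nrow(data)
  if (n > 600L) stop("dense-kernel GP fit limited to n <= 600")
  if (!is.null(seed)) set.seed(seed)
  feats <- rf_feature_names(data)
  Zraw <- as.matrix(data[, feats, drop = FALSE])
  ctr <- colMeans(Zraw)
  scl <- apply(Zraw, 2, sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(Zraw, 2, ctr), 2, scl, "/")
  p <- ncol(Z)
  dists <- sqdist_by_dim(Z, Z)
  ycell <- 1L + data$E + 2L * data$T # 1=00, 2=10, 3=01, 4=11

  n_keep <- chains * iter
  out <- list(
    fE = matrix(NA_real_, n_keep, n), fT = matrix(NA_real_, n_keep, n),
    a = numeric(n_keep), b = numeric(n_keep),
    hypE = matrix(NA_real_, n_keep, 2 * p + 2),
    hypT = matrix(NA_real_, n_keep, 2 * p + 2),
    alpha = rep(if (mode == "copula") NA_real_ else 0, n_keep),
    loglik = numeric(n_keep), chain = rep(seq_len(chains), each = iter)
  )
  trace_names <- c("a", "b", "eta_E", "eta_T", "tau_E", "tau_T", "loglik")
  traces <- vector("list", chains)
  rm_gain <- function(t) min(0.25, 3 / sqrt(t)) # Robbins-Monro step size

  for (ch in seq_len(chains)) {
    hE <- list(leta = 0, rho = rnorm(p, 0, 0.3), llam = rep(0, p), ltau = 0)
    hT <- list(leta = 0, rho = rnorm(p, 0, 0.3), llam = rep(0, p), ltau = 0)
    zeta <- 0
    # whitened latents; the last element is the probit intercept (a or b),
    # which shares the standard-normal prior and is updated by the same
    # elliptical slice step
    uE <- c(rnorm(n, 0, 0.1),
            qnorm(max(0.02, min(0.98, mean(data$E == 0)))))
    uT <- c(rnorm(n, 0, 0.1),
            qnorm(max(0.02, min(0.98, mean(data$T == 0)))))
    LE <- chol_jitter(kernel_from_dists(dists, exp(hE$leta), hE$rho), jitter)
    LT <- chol_jitter(kernel_from_dists(dists, exp(hT$leta), hT$rho), jitter)
    fE <- as.vector(LE %*% uE[1:n]); fT <- as.vector(LT %*% uT[1:n])
    alpha <- if (mode == "copula") 0.99 * tanh(zeta) else 0
    ll <- gp_loglik(fE, fT, uE[n + 1], uT[n + 1], mode, alpha, ycell)
    sE <- 0.1; sT <- 0.1; sS <- 0.4; sz <- 0.3 # adaptive proposal scales
    tr <- matrix(NA_real_, iter, length(trace_names))

    total <- warmup + iter
    for (t in seq_len(total)) {
      # latent + intercept updates (whitened elliptical slice sampling)
      r <- ess_step(uE, function(u) {
        gp_loglik(as.vector(LE %*% u[1:n]), fT, u[n + 1], uT[n + 1], mode,
                  alpha, ycell)
      }, ll)
      uE <- r$u; fE <- as.vector(LE %*% uE[1:n]); ll <- r$ll
      r <- ess_step(uT, function(u) {
        gp_loglik(fE, as.vector(LT %*% u[1:n]), uE[n + 1], u[n + 1], mode,
                  alpha, ycell)
      }, ll)
      uT <- r$u; fT <- as.vector(LT %*% uT[1:n]); ll <- r$ll

      # kernel blocks (signal magnitude + ARD weights); the whitened
      # parameterization keeps the latent prior fixed under these moves
      kb <- c(hE$leta, hE$rho)
      prop <- hE; prop$leta <- kb[1] + sE * rnorm(1) * 0.5
      prop$rho <- kb[-1] + sE * rnorm(p)
      LEp <- tryCatch(chol_jitter(
        kernel_from_dists(dists, exp(prop$leta), prop$rho), jitter),
        error = function(e) NULL)
      if (!is.null(LEp)) {
        fEp <- as.vector(LEp %*% uE[1:n])
        llp <- gp_loglik(fEp, fT, uE[n + 1], uT[n + 1], mode, alpha, ycell)
        acc <- llp + gp_kernel_lp(prop) - ll - gp_kernel_lp(hE)
        if (is.finite(acc) && log(runif(1)) < acc) {
          hE <- prop; LE <- LEp; fE <- fEp; ll <- llp
          if (t <= warmup) sE <- sE * exp(rm_gain(t) * 0.7)
        } else if (t <= warmup) sE <- sE * exp(-rm_gain(t) * 0.3)
      }
      kb <- c(hT$leta, hT$rho)
      prop <- hT; prop$leta <- kb[1] + sT * rnorm(1) * 0.5
      prop$rho <- kb[-1] + sT * rnorm(p)
      LTp <- tryCatch(chol_jitter(
        kernel_from_dists(dists, exp(prop$leta), prop$rho), jitter),
        error = function(e) NULL)
      if (!is.null(LTp)) {
        fTp <- as.vector(LTp %*% uT[1:n])
        llp <- gp_loglik(fE, fTp, uE[n + 1], uT[n + 1], mode, alpha, ycell)
        acc <- llp + gp_kernel_lp(prop) - ll - gp_kernel_lp(hT)
        if (is.finite(acc) && log(runif(1)) < acc) {
          hT <- prop; LT <- LTp; fT <- fTp; ll <- llp
          if (t <= warmup) sT <- sT * exp(rm_gain(t) * 0.7)
        } else if (t <= warmup) sT <- sT * exp(-rm_gain(t) * 0.3)
      }

      # horseshoe-scale blocks: conditional on rho, independent of the
      # data, so several cheap Metropolis refreshes per sweep
      for (rep_s in 1:3) {
        for (side in c("E", "T")) {
          h <- if (side == "E") hE else hT
          prop <- h
          prop$llam <- h$llam + sS * rnorm(p)
          prop$ltau <- h$ltau + sS * rnorm(1)
          acc <- gp_scales_lp(prop) - gp_scales_lp(h)
          if (is.finite(acc) && log(runif(1)) < acc) {
            if (side == "E") hE <- prop else hT <- prop
            if (t <= warmup) sS <- sS * exp(rm_gain(t) * 0.7 / 3)
          } else if (t <= warmup) sS <- sS * exp(-rm_gain(t) * 0.3 / 3)
        }
      }

      # copula correlation
      if (mode == "copula") {
        zp <- zeta + sz * rnorm(1)
        ap <- 0.99 * tanh(zp)
        llp <- gp_loglik(fE, fT, uE[n + 1], uT[n + 1], mode, ap, ycell)
        acc <- llp + dnorm(zp, log = TRUE) - ll - dnorm(zeta, log = TRUE)
        if (is.finite(acc) && log(runif(1)) < acc) {
          zeta <- zp; alpha <- ap; ll <- llp
          if (t <= warmup) sz <- sz * exp(rm_gain(t) * 0.7)
        } else if (t <= warmup) sz <- sz * exp(-rm_gain(t) * 0.3)
      }

      if (t > warmup) {
        k <- (ch - 1L) * iter + (t - warmup)
        out$fE[k, ] <- fE; out$fT[k, ] <- fT
        out$a[k] <- uE[n + 1]; out$b[k] <- uT[n + 1]
        out$hypE[k, ] <- hyp_pack(hE); out$hypT[k, ] <- hyp_pack(hT)
        out$alpha[k] <- alpha; out$loglik[k] <- ll
        tr[t - warmup, ] <- c(uE[n + 1], uT[n + 1], exp(hE$leta),
                              exp(hT$leta), exp(hE$ltau), exp(hT$ltau), ll)
      }
    }
    colnames(tr) <- trace_names
    traces[[ch]] <- coda::mcmc(tr)
    if (verbose) message("chain ", ch, " done (scales ", round(sE, 3), "/",
                         round(sT, 3), ")")
  }

  mcl <- coda::mcmc.list(traces)
  ess <- tryCatch(coda::effectiveSize(mcl), error = function(e) NULL)
  rhat <- if (chains >= 2L) {
    tryCatch(coda::gelman.diag(mcl, autoburnin = FALSE,
                               multivariate = FALSE)$psrf[, 1],
             error = function(e) rep(NA_real_, length(trace_names)))
  } else rep(NA_real_, length(trace_names))
  diag_df <- data.frame(parameter = trace_names, rhat = rhat,
                        ess = if (is.null(ess)) NA_real_ else as.numeric(ess))

  structure(list(draws = out, mode = mode, p = p, n = n, Z = Z, ctr = ctr,
                 scl = scl, features = feats, dists = dists, jitter = jitter,
                 chains = chains, iter = iter, diagnostics = diag_df),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Gaussian-process probit fit (", x$mode, " joint), n = ", x$n,
      ", ", x$chains, " chain(s) x ", x$iter, " draws\n", sep = "")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

# posterior-mean marginal probabilities at the training points
gp_train_pE <- function(fit) {
  1 - colMeans(pnorm(fit$draws$fE + fit$draws$a))
}
gp_train_pT <- function(fit) {
  1 - colMeans(pnorm(fit$draws$fT + fit$draws$b))
}

# standardize new (covariate, dose-grid) inputs for one patient
gp_new_inputs <- function(fit, x, grid) {
  covs <- setdiff(fit$features, "dose")
  x <- unlist(x)
  if (!all(covs %in% names(x))) stop("x must name covariates: ",
                                     paste(covs, collapse = ", "))
  Znew <- cbind(matrix(rep(as.numeric(x[covs]), each = length(grid)),
                       length(grid), length(covs),
                       dimnames = list(NULL, covs)),
                dose = grid)
  sweep(sweep(Znew, 2, fit$ctr), 2, fit$scl, "/")
}

# conditional draw of latent values at D new inputs given one posterior
# draw; returns length-D vector
gp_cond_draw <- function(L, f, Kstar, Kss, jitter) {
  V <- forwardsolve(L, Kstar)              # n x D
  m <- as.vector(crossprod(V, forwardsolve(L, f)))
  C <- Kss - crossprod(V)
  Lc <- chol_jitter((C + t(C)) / 2, jitter)
  m + as.vector(Lc %*% rnorm(ncol(Kstar)))
}

#' Posterior predictive joint probabilities over a dose grid
#'
#' For each retained posterior draw, latent values at the patient's
#' covariates and every grid dose are drawn from the Gaussian conditional
#' given that draw's training latents and kernel hyperparameters (a full
#' conditional draw, not just the mean, so posterior uncertainty
#' propagates into the dose-selection rules), then mapped through the
#' probit link and the joint construction.
#'
#' @param fit A [fit_gp()] object.
#' @param x Named covariate vector for the new patient.
#' @param grid Dose grid.
#' @param n_draws Number of posterior draws to use (default: all;
#'   thinned evenly when fewer are requested).
#' @return A [posterior_draws()] object (`n_draws x D x 4`).
#' @export
posterior_predictive <- function(fit, x, grid, n_draws = NULL) {
  stopifnot(inherits(fit, "gp_fit"))
  S_all <- nrow(fit$draws$fE)
  idx <- if (is.null(n_draws) || n_draws >= S_all) seq_len(S_all) else
    unique(round(seq(1, S_all, length.out = n_draws)))
  S <- length(idx)
  D <- length(grid)
  Znew <- gp_new_inputs(fit, x, grid)
  dists_sn <- sqdist_by_dim(fit$Z, Znew)
  dists_nn <- sqdist_by_dim(Znew, Znew)
  arr <- array(NA_real_, c(S, D, 4))
  p <- fit$p
  for (s in seq_len(S)) {
    k <- idx[s]
    hE <- hyp_unpack(fit$draws$hypE[k, ], p)
    hT <- hyp_unpack(fit$draws$hypT[k, ], p)
    LE <- chol_jitter(kernel_from_dists(fit$dists, exp(hE$leta), hE$rho),
                      fit$jitter)
    LT <- chol_jitter(kernel_from_dists(fit$dists, exp(hT$leta), hT$rho),
                      fit$jitter)
    fEn <- gp_cond_draw(LE, fit$draws$fE[k, ],
                        kernel_from_dists(dists_sn, exp(hE$leta), hE$rho),
                        kernel_from_dists(dists_nn, exp(hE$leta), hE$rho),
                        fit$jitter)
    fTn <- gp_cond_draw(LT, fit$draws$fT[k, ],
                        kernel_from_dists(dists_sn, exp(hT$leta), hT$rho),
                        kernel_from_dists(dists_nn, exp(hT$leta), hT$rho),
                        fit$jitter)
    arr[s, , ] <- gp_cells(fEn + fit$draws$a[k], fTn + fit$draws$b[k],
                           fit$mode, fit$draws$alpha[k])
  }
  posterior_draws(arr, grid,
                  alpha = if (fit$mode == "copula") fit$draws$alpha[idx])
}

# recommend doses for many patients under a posterior rule; draw-outer loop
# so the training Cholesky is reused across patients. Returns a dose per
# patient.
gp_rule_doses <- function(fit, Xcov, grid, cfg,
                          rule = c("posterior_mean", "posterior_prob"),
                          d_fix = cfg$d_fix, n_draws = 200L) {
  rule <- match.arg(rule)
  npat <- nrow(Xcov); D <- length(grid); p <- fit$p
  covs <- setdiff(fit$features, "dose")
  S_all <- nrow(fit$draws$fE)
  idx <- if (n_draws >= S_all) seq_len(S_all) else
    unique(round(seq(1, S_all, length.out = n_draws)))
  Zn <- vector("list", npat)
  for (i in seq_len(npat)) {
    Zn[[i]] <- gp_new_inputs(fit, stats::setNames(as.numeric(Xcov[i, covs]),
                                                  covs), grid)
  }
  usum <- matrix(0, npat, D)
  ucount <- matrix(0, npat, D)
  jfix <- if (rule == "posterior_prob") {
    if (is.null(d_fix)) stop("posterior_prob rule requires d_fix")
    which.min(abs(grid - d_fix))
  } else NA_integer_
  m <- cfg$matrix
  for (s in idx) {
    hE <- hyp_unpack(fit$draws$hypE[s, ], p)
    hT <- hyp_unpack(fit$draws$hypT[s, ], p)
    LE <- chol_jitter(kernel_from_dists(fit$dists, exp(hE$leta), hE$rho),
                      fit$jitter)
    LT <- chol_jitter(kernel_from_dists(fit$dists, exp(hT$leta), hT$rho),
                      fit$jitter)
    wE <- forwardsolve(LE, fit$draws$fE[s, ])
    wT <- forwardsolve(LT, fit$draws$fT[s, ])
    for (i in seq_len(npat)) {
      dsn <- sqdist_by_dim(fit$Z, Zn[[i]])
      dnn <- sqdist_by_dim(Zn[[i]], Zn[[i]])
      VE <- forwardsolve(LE, kernel_from_dists(dsn, exp(hE$leta), hE$rho))
      VT <- forwardsolve(LT, kernel_from_dists(dsn, exp(hT$leta), hT$rho))
      CE <- kernel_from_dists(dnn, exp(hE$leta), hE$rho) - crossprod(VE)
      CT <- kernel_from_dists(dnn, exp(hT$leta), hT$rho) - crossprod(VT)
      fEn <- as.vector(crossprod(VE, wE)) +
        as.vector(chol_jitter((CE + t(CE)) / 2, fit$jitter) %*% rnorm(D))
      fTn <- as.vector(crossprod(VT, wT)) +
        as.vector(chol_jitter((CT + t(CT)) / 2, fit$jitter) %*% rnorm(D))
      cells <- gp_cells(fEn + fit$draws$a[s], fTn + fit$draws$b[s], fit$mode,
                        fit$draws$alpha[s])
      pE <- cells[, "p10"] + cells[, "p11"]
      pT <- cells[, "p01"] + cells[, "p11"]
      u <- utility_from_marginals(pE, pT, cells[, "p11"], m)
      if (cfg$rule == "tox_cap") {
        u <- u - cfg$tox_multiplier * m$omega1 * pT * (pT >= cfg$tox_threshold)
      } else if (cfg$rule == "dose_penalty") {
        u <- u - cfg$delta * (grid - cfg$d_fix)^2
      }
      usum[i, ] <- usum[i, ] + u
      if (rule == "posterior_prob") {
        ucount[i, ] <- ucount[i, ] + (u > u[jfix])
      }
    }
  }
  score <- if (rule == "posterior_mean") usum else ucount
  argmax_dose(score, grid)
}
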