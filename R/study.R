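# Replication loop of the simulation study: generate training data, fit the
# requested model/rule combinations, recommend doses for an independent
# validation set, and score every recommendation under the generative
# truth.
#
# Method catalogue (as compared in the study):
#   M1  truth (oracle)                   M7  monotone RF + dose penalty
#   M2  RF marginals + copula            M8  RF on the 4-category outcome
#   M3  RF marginals, independence       M9  M8 + PAVA joint adjustment
#   M4  monotone RF + copula             M10 GP, posterior-probability rule
#   M5  monotone RF, independence        M11 GP, posterior-mean rule
#   M6  monotone RF + toxicity cap       M12 fixed dose (dose-only multinomial)

RF_METHODS_PLAIN <- c("M2", "M3")
RF_METHODS_MONO <- c("M4", "M5", "M6", "M7")
RF_METHODS_CAT <- c("M8", "M9")
GP_METHODS <- c("M10", "M11")

#' Study configuration
#'
#' @param scenario Scenario id (`"S0"`-`"S10"`) or a [true_model_spec()].
#' @param methods Character vector of method ids (`"M1"`-`"M12"`). `M1`
#'   and `M12` are always computed (they anchor the improvement metric).
#' @param utilities List of `c(omega1, omega2)` pairs.
#' @param R Number of replicates.
#' @param n_train,n_valid Training and validation sizes (validation
#'   defaults to the training size).
#' @param grid Dose grid.
#' @param seed Integer master seed; per-replicate substream seeds are
#'   drawn from it so replicates are reproducible individually.
#' @param delta Dose-penalty weight for `M7`.
#' @param rf_opts,gp_opts Option lists forwarded to the model fitters
#'   (`rf_opts$num_trees`; `gp_opts$chains`, `$warmup`, `$iter`,
#'   `$n_draws`, `$grid_n` for a coarser GP prediction grid).
#' @return Object of class `study_config`.
#' @export
study_config <- function(scenario = "S1", methods = c("M1", "M12"),
                         utilities = list(c(0.3, 0.5), c(0.5, 0.5),
                                          c(0.5, 0.3)),
                         R = 1000L, n_train = 200L, n_valid = n_train,
                         grid = dose_grid(), seed = 1L, delta = 0.1,
                         rf_opts = list(), gp_opts = list()) {
  spec <- if (inherits(scenario, "true_model_spec")) scenario else
    scenario_spec(scenario)
  methods <- union(c("M1", "M12"), methods)
  bad <- setdiff(methods, paste0("M", 1:12))
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  structure(list(spec = spec, scenario = if (is.character(scenario))
    scenario else "custom", methods = methods, utilities = utilities,
    R = as.integer(R), n_train = as.integer(n_train),
    n_valid = as.integer(n_valid), grid = grid, seed = as.integer(seed),
    delta = delta, rf_opts = rf_opts, gp_opts = gp_opts),
    class = "study_config")
}

# utility surface over patients x grid from estimated marginal matrices
est_utility_surface <- function(pEm, pTm, alpha, cfg, grid) {
  m <- cfg$matrix
  need_p11 <- abs(m$omega1 + m$omega2 - 1) > 1e-12 || cfg$rule == "tox_cap"
  p11 <- 0
  if (need_p11 || !is.null(alpha)) {
    j <- joint_from_marginals(as.vector(pEm), as.vector(pTm),
                              if (is.null(alpha)) copula_spec(0, "independence")
                              else copula_spec(alpha))
    p11 <- matrix(j$p11, nrow(pEm), ncol(pEm))
  }
  u <- utility_from_marginals(pEm, pTm, p11, m)
  if (cfg$rule == "tox_cap") {
    u <- u - cfg$tox_multiplier * m$omega1 * pTm * (pTm >= cfg$tox_threshold)
  } else if (cfg$rule == "dose_penalty") {
    u <- u - matrix(cfg$delta * (grid - cfg$d_fix)^2, nrow(u), ncol(u),
                    byrow = TRUE)
  }
  u
}

# one replicate: returns data.frame of rows (utility x method)
study_replicate <- function(cfg, rep_seed) {
  set.seed(rep_seed)
  spec <- cfg$spec
  grid <- cfg$grid
  train <- generate_dataset(spec, cfg$n_train)
  valid <- generate_dataset(spec, cfg$n_valid)
  Xv <- covariate_matrix(valid, spec$Q)
  Xv_df <- as.data.frame(Xv)
  methods <- cfg$methods
  nt <- cfg$rf_opts$num_trees %||% 500L

  fits <- list()
  if (any(RF_METHODS_PLAIN %in% methods)) {
    fits$rfE <- fit_marginal_rf(train, "E", num_trees = nt)
    fits$rfT <- fit_marginal_rf(train, "T", num_trees = nt)
    fits$alpha_plain <- estimate_alpha(train$E, train$T, fits$rfE$oob,
                                       fits$rfT$oob)
    fits$pE_plain <- predict_marginal_curves(fits$rfE, Xv_df, grid)
    fits$pT_plain <- predict_marginal_curves(fits$rfT, Xv_df, grid)
  }
  if (any(RF_METHODS_MONO %in% methods)) {
    fits$rfEm <- fit_marginal_rf(train, "E", monotone_in_dose = TRUE,
                                 num_trees = nt)
    fits$rfTm <- fit_marginal_rf(train, "T", monotone_in_dose = TRUE,
                                 num_trees = nt)
    fits$alpha_mono <- estimate_alpha(train$E, train$T, fits$rfEm$oob,
                                      fits$rfTm$oob)
    fits$pE_mono <- predict_marginal_curves(fits$rfEm, Xv_df, grid)
    fits$pT_mono <- predict_marginal_curves(fits$rfTm, Xv_df, grid)
  }
  if (any(RF_METHODS_CAT %in% methods)) {
    fits$rfc <- fit_categorical_rf(train, num_trees = nt)
    D <- length(grid)
    Xrep <- cbind(Xv[rep(seq_len(nrow(Xv)), each = D), , drop = FALSE],
                  dose = rep(grid, nrow(Xv)))
    colnames(Xrep) <- c(colnames(Xv), "dose")
    fits$cat_cells <- predict_categorical_prob(fits$rfc, Xrep)
  }
  if (any(GP_METHODS %in% methods)) {
    go <- cfg$gp_opts
    fits$gp <- fit_gp(train, mode = go$mode %||% "independence",
                      chains = go$chains %||% 2L,
                      warmup = go$warmup %||% 300L,
                      iter = go$iter %||% 300L)
    fits$gp_grid <- if (!is.null(go$grid_n)) {
      dose_grid(min(grid), max(grid), go$grid_n)
    } else grid
  }

  rows <- list()
  for (ui in seq_along(cfg$utilities)) {
    om <- cfg$utilities[[ui]]
    ucfg <- utility_config(utility_matrix(om[1], om[2]))
    fd <- fixed_dose_rule(train, grid, ucfg)
    doses <- list()
    doses$M1 <- oracle_rule(spec, Xv, grid, ucfg)
    doses$M12 <- rep(fd$d_fix, nrow(valid))
    for (mth in setdiff(methods, c("M1", "M12"))) {
      doses[[mth]] <- tryCatch(
        recommend_method(mth, fits, ucfg, grid, Xv, fd$d_fix, cfg$delta),
        error = function(e) {
          warning("replicate method ", mth, " failed: ",
                  conditionMessage(e))
          NULL
        })
    }
    for (mth in names(doses)) {
      if (is.null(doses[[mth]])) next
      ev <- evaluate_rule(spec, valid, doses[[mth]], ucfg)
      ev$method <- mth
      ev$utility <- paste0("U", ui)
      rows[[paste(ui, mth)]] <- ev
    }
  }
  out <- do.call(rbind, rows)
  out$pct_improvement <- NA_real_
  # percent improvement within the replicate, anchored at M1/M12
  for (ui in unique(out$utility)) {
    sel <- out$utility == ui
    u_true <- out$mean_utility[sel & out$method == "M1"]
    u_fix <- out$mean_utility[sel & out$method == "M12"]
    out$pct_improvement[sel] <- pct_improvement(out$mean_utility[sel],
                                                u_fix, u_true)
  }
  out$rep_seed <- rep_seed
  out
}

recommend_method <- function(mth, fits, ucfg, grid, Xv, d_fix, delta) {
  switch(mth,
    M2 = argmax_dose(est_utility_surface(fits$pE_plain, fits$pT_plain,
                                         fits$alpha_plain, ucfg, grid), grid),
    M3 = argmax_dose(est_utility_surface(fits$pE_plain, fits$pT_plain,
                                         NULL, ucfg, grid), grid),
    M4 = argmax_dose(est_utility_surface(fits$pE_mono, fits$pT_mono,
                                         fits$alpha_mono, ucfg, grid), grid),
    M5 = argmax_dose(est_utility_surface(fits$pE_mono, fits$pT_mono,
                                         NULL, ucfg, grid), grid),
    M6 = {
      c6 <- utility_config(ucfg$matrix, rule = "tox_cap")
      argmax_dose(est_utility_surface(fits$pE_mono, fits$pT_mono,
                                      fits$alpha_mono, c6, grid), grid)
    },
    M7 = {
      c7 <- utility_config(ucfg$matrix, rule = "dose_penalty", delta = delta,
                           d_fix = d_fix)
      argmax_dose(est_utility_surface(fits$pE_mono, fits$pT_mono,
                                      fits$alpha_mono, c7, grid), grid)
    },
    M8 = {
      D <- length(grid)
      p11 <- matrix(fits$cat_cells[, "p11"], ncol = D, byrow = TRUE)
      pE <- matrix(fits$cat_cells[, "p10"] + fits$cat_cells[, "p11"],
                   ncol = D, byrow = TRUE)
      pT <- matrix(fits$cat_cells[, "p01"] + fits$cat_cells[, "p11"],
                   ncol = D, byrow = TRUE)
      argmax_dose(utility_from_marginals(pE, pT, p11, ucfg$matrix), grid)
    },
    M9 = {
      D <- length(grid)
      n <- nrow(fits$cat_cells) / D
      vapply(seq_len(n), function(i) {
        rowsel <- ((i - 1) * D + 1):(i * D)
        cells <- fits$cat_cells[rowsel, , drop = FALSE]
        curve <- joint_prob(cells[, "p00"], cells[, "p10"], cells[, "p01"],
                            cells[, "p11"], dose = grid, tol = 1e-6)
        adj <- adjust_joint_p11(curve, "p11_only")$adjusted
        optimal_dose_pointwise(adj, ucfg)$dose
      }, numeric(1))
    },
    M10 = gp_rule_doses(fits$gp, Xv, fits$gp_grid, ucfg, "posterior_prob",
                        d_fix = d_fix,
                        n_draws = fits$gp$iter),
    M11 = gp_rule_doses(fits$gp, Xv, fits$gp_grid, ucfg, "posterior_mean",
                        n_draws = fits$gp$iter),
    stop("unknown method ", mth)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulation study
#'
#' Iterates the replication loop (generate training data, fit, generate
#' validation data, recommend, score under the truth) and averages the
#' metrics over replicates. The improvement metric is computed within each
#' replicate against that replicate's oracle and fixed-dose utilities,
#' then averaged.
#'
#' @param cfg A [study_config()].
#' @param checkpoint_dir Optional directory; per-replicate results are
#'   written there as CSV and completed replicates are skipped on rerun.
#' @param verbose Print per-replicate progress.
#' @return `data.frame` with one row per utility x method: `mean_dose`,
#'   `sd_dose`, `mean_E`, `mean_T`, `mean_utility` (x100 scale),
#'   `pct_improvement`, `n_reps`, `n_fail`.
#' @export
run_study <- function(cfg, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$R)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  reps <- vector("list", cfg$R)
  for (r in seq_len(cfg$R)) {
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("rep_%04d.csv", r)) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      reps[[r]] <- utils::read.csv(ck)
    } else {
      reps[[r]] <- study_replicate(cfg, rep_seeds[r])
      if (!is.null(ck)) utils::write.csv(reps[[r]], ck, row.names = FALSE)
    }
    if (verbose) message("replicate ", r, "/", cfg$R)
  }
  all <- do.call(rbind, reps)
  expected <- expand.grid(method = cfg$methods,
                          utility = paste0("U", seq_along(cfg$utilities)),
                          stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(expected)), function(i) {
    sel <- all$method == expected$method[i] & all$utility == expected$utility[i]
    sub <- all[sel, , drop = FALSE]
    data.frame(
      utility = expected$utility[i], method = expected$method[i],
      mean_dose = mean(sub$mean_dose), sd_dose = mean(sub$sd_dose),
      mean_E = mean(sub$mean_E), mean_T = mean(sub$mean_T),
      mean_utility = mean(sub$mean_utility),
      pct_improvement = mean(sub$pct_improvement),
      n_reps = nrow(sub), n_fail = cfg$R - nrow(sub)
    )
  }))
  ord <- order(out$utility, as.integer(sub("^M", "", out$method)))
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  out
}
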