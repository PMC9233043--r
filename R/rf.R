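# Random-forest estimation of the outcome probabilities.
#
# Unconstrained marginal models and the 4-category joint model use ranger
# probability forests (true out-of-bag probabilities). Marginal models
# constrained to be nondecreasing in dose use xgboost in random-forest mode
# (one boosting round of many parallel trees, row subsampling and per-node
# column subsampling) because its per-feature monotone-constraint facility
# enforces the constraint inside the tree learner; their "out-of-bag" table
# is built by 5-fold cross-fitting since bagged xgboost exposes no OOB
# predictions.

PRED_CLIP <- 1e-6 # keeps copula probit transforms finite

clip_prob <- function(p) pmin(pmax(p, PRED_CLIP), 1 - PRED_CLIP)

rf_feature_names <- function(data) {
  xs <- grep("^x[0-9]+$", names(data), value = TRUE)
  c(xs[order(as.integer(sub("^x", "", xs)))], "dose")
}

#' Fit a random-forest marginal model for efficacy or toxicity
#'
#' @param data Patient table with covariate columns `x1..xQ`, `dose`, and
#'   outcome columns `E`, `T`.
#' @param outcome `"E"` or `"T"`.
#' @param monotone_in_dose Constrain the predicted probability to be
#'   nondecreasing in dose (xgboost random-forest backend).
#' @param num_trees Ensemble size (default 500).
#' @param mtry Features sampled per split (default: floor(sqrt(p))).
#' @param max_depth Tree depth cap for the xgboost backend (default 10).
#' @param n_folds Folds for the cross-fitted out-of-fold table of the
#'   monotone backend.
#' @param seed Integer seed for the ensemble.
#' @return Object of class `marginal_model` with the fitted ensemble, the
#'   feature names, and `oob`: out-of-bag (ranger) or out-of-fold
#'   (xgboost) probabilities for every training row, used when the
#'   training set itself must be scored (for example copula-correlation
#'   estimation).
#' @export
fit_marginal_rf <- function(data, outcome = c("E", "T"),
                            monotone_in_dose = FALSE, num_trees = 500L,
                            mtry = NULL, max_depth = 10L, n_folds = 5L,
                            seed = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(nrow(data) >= 20L, "dose" %in% names(data),
            outcome %in% names(data))
  feats <- rf_feature_names(data)
  y <- data[[outcome]]
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) == 1L) {
    warning("outcome ", outcome, " is constant; degenerate model")
    return(structure(list(outcome = outcome, monotone = monotone_in_dose,
                          backend = "constant", rate = y[1], features = feats,
                          oob = rep(clip_prob(y[1]), nrow(data))),
                     class = "marginal_model"))
  }
  X <- as.matrix(data[, feats, drop = FALSE])
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(feats))))
  if (!is.null(seed)) set.seed(seed)
  if (monotone_in_dose) {
    params <- list(booster = "gbtree", objective = "binary:logistic",
                   eta = 1, num_parallel_tree = num_trees, subsample = 0.632,
                   colsample_bynode = mtry / length(feats),
                   max_depth = max_depth,
                   monotone_constraints = paste0(
                     "(", paste(as.integer(feats == "dose"), collapse = ","),
                     ")"))
    fit <- xgboost::xgb.train(params = params,
                              data = xgboost::xgb.DMatrix(X, label = y),
                              nrounds = 1L, verbose = 0)
    # out-of-fold probabilities for the training rows
    fold <- sample(rep_len(seq_len(n_folds), nrow(X)))
    oob <- numeric(nrow(X))
    for (k in seq_len(n_folds)) {
      hold <- fold == k
      fk <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(X[!hold, , drop = FALSE],
                                    label = y[!hold]),
        nrounds = 1L, verbose = 0)
      oob[hold] <- predict(fk, xgboost::xgb.DMatrix(X[hold, , drop = FALSE]))
    }
    backend <- "xgboost"
  } else {
    fit <- ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                          probability = TRUE, num.trees = num_trees,
                          mtry = mtry,
                          seed = if (is.null(seed)) sample.int(1e6, 1) else seed)
    oob <- fit$predictions[, "1"]
    if (anyNA(oob)) { # rows never out of bag
      filled <- predict(fit, data = X)$predictions[, "1"]
      oob[is.na(oob)] <- filled[is.na(oob)]
    }
    backend <- "ranger"
  }
  structure(list(outcome = outcome, monotone = monotone_in_dose,
                 backend = backend, fit = fit, features = feats,
                 oob = clip_prob(oob)),
            class = "marginal_model")
}

# probability predictions at arbitrary rows (matrix with model features)
predict_marginal_prob <- function(model, X) {
  stopifnot(inherits(model, "marginal_model"))
  if (!all(model$features %in% colnames(X))) {
    stop("newdata lacks features: ",
         paste(setdiff(model$features, colnames(X)), collapse = ", "))
  }
  X <- X[, model$features, drop = FALSE]
  p <- switch(model$backend,
    constant = rep(model$rate, nrow(X)),
    xgboost = predict(model$fit, xgboost::xgb.DMatrix(X)),
    ranger = predict(model$fit, data = X)$predictions[, "1"]
  )
  clip_prob(p)
}

#' Predicted marginal dose-curve for one patient
#'
#' @param model A fitted [fit_marginal_rf()] model.
#' @param x Named covariate vector (or one-row data frame) for the patient.
#' @param grid Dose grid.
#' @return Probability per grid point, clipped to `[1e-6, 1 - 1e-6]`.
#' @export
predict_marginal_curve <- function(model, x, grid) {
  x <- unlist(x)
  covs <- setdiff(model$features, "dose")
  if (!all(covs %in% names(x))) stop("x must name all model covariates")
  X <- cbind(matrix(rep(as.numeric(x[covs]), each = length(grid)),
                    length(grid), length(covs),
                    dimnames = list(NULL, covs)),
             dose = grid)
  predict_marginal_prob(model, X)
}

# curves for many patients at once: returns patients x grid matrix
predict_marginal_curves <- function(model, Xcov, grid) {
  n <- nrow(Xcov); D <- length(grid)
  covs <- setdiff(model$features, "dose")
  X <- cbind(Xcov[rep(seq_len(n), each = D), covs, drop = FALSE],
             dose = rep(grid, n))
  matrix(predict_marginal_prob(model, X), n, D, byrow = TRUE)
}

#' Fit a random forest on the four-category joint outcome
#'
#' Models the joint cell probabilities `(p00, p10, p01, p11)` directly as a
#' 4-class probability forest on covariates and dose.
#'
#' @inheritParams fit_marginal_rf
#' @return Object of class `categorical_model`.
#' @export
fit_categorical_rf <- function(data, num_trees = 500L, mtry = NULL,
                               seed = NULL) {
  stopifnot(nrow(data) >= 20L, all(c("dose", "E", "T") %in% names(data)))
  feats <- rf_feature_names(data)
  lv <- c("00", "10", "01", "11")
  y <- factor(paste0(data$E, data$T), levels = lv)
  missing_classes <- lv[!lv %in% y]
  if (length(missing_classes)) {
    message("classes absent from training data: ",
            paste(missing_classes, collapse = ", "))
  }
  X <- as.matrix(data[, feats, drop = FALSE])
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(feats))))
  fit <- ranger::ranger(x = X, y = droplevels(y), probability = TRUE,
                        num.trees = num_trees, mtry = mtry,
                        seed = if (is.null(seed)) sample.int(1e6, 1) else seed)
  structure(list(fit = fit, features = feats, classes = lv,
                 oob = fit$predictions),
            class = "categorical_model")
}

# 4-class probabilities at rows; columns p00, p10, p01, p11 (classes 00,
# 10, 01, 11); classes absent from training get probability 0
predict_categorical_prob <- function(model, X) {
  stopifnot(inherits(model, "categorical_model"))
  X <- X[, model$features, drop = FALSE]
  pr <- predict(model$fit, data = X)$predictions
  out <- matrix(0, nrow(X), 4, dimnames = list(NULL, model$classes))
  out[, colnames(pr)] <- pr
  out <- out / rowSums(out)
  colnames(out) <- c("p00", "p10", "p01", "p11")
  out
}

#' Predicted joint-probability dose-curve for one patient
#'
#' @param model A fitted [fit_categorical_rf()] model.
#' @param x Named covariate vector for the patient.
#' @param grid Dose grid.
#' @return A [joint_prob()] with one row per grid point.
#' @export
predict_joint_curve <- function(model, x, grid) {
  x <- unlist(x)
  covs <- setdiff(model$features, "dose")
  if (!all(covs %in% names(x))) stop("x must name all model covariates")
  X <- cbind(matrix(rep(as.numeric(x[covs]), each = length(grid)),
                    length(grid), length(covs),
                    dimnames = list(NULL, covs)),
             dose = grid)
  pr <- predict_categorical_prob(model, X)
  joint_prob(pr[, "p00"], pr[, "p10"], pr[, "p01"], pr[, "p11"],
             dose = grid, tol = 1e-6)
}
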