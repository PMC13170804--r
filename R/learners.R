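# The three learners behind the monthly ensembles. All accept a numeric
# predictor matrix with named columns and a numeric response (already on
# log scale upstream). Fits are reproducible under set.seed(): the tree
# engines draw from R's RNG stream and the SVR is deterministic.

as_predictor_matrix <- function(x, predictors = NULL) {
  if (is.data.frame(x)) {
    if (!is.null(predictors)) {
      missing <- setdiff(predictors, names(x))
      if (length(missing))
        stop("missing predictors: ", paste(missing, collapse = ", "))
      x <- x[predictors]
    }
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("predictor matrix contains missing values")
  x
}

#' Fit a random-forest regressor
#'
#' Bagged CART regression trees with per-node feature subsampling.
#' Importance is the mean increase in out-of-bag MSE when a predictor is
#' permuted (the %IncMSE measure, unscaled).
#'
#' @param x numeric matrix or data frame of predictors (named columns).
#' @param y numeric response.
#' @param ntree number of trees.
#' @param mtry features tried per split; default `max(1, floor(p / 3))`.
#' @param min_node minimum node size eligible for splitting.
#' @param max_depth maximum tree depth (0 = unlimited).
#' @return object of class `rc_rf` with `$importance` and `$oob_pred`.
#' @export
fit_rf <- function(x, y, ntree = 100, mtry = NULL, min_node = 5,
                   max_depth = 0) {
  x <- as_predictor_matrix(x)
  stopifnot(nrow(x) == length(y))
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(x) / 3))
  fit <- .forest_fit(x, as.numeric(y), as.integer(ntree), as.integer(mtry),
                     as.integer(min_node), as.integer(max_depth))
  structure(list(trees = fit$trees,
                 importance = setNames(fit$importance, colnames(x)),
                 oob_pred = fit$oob_pred, predictors = colnames(x),
                 hyper = list(ntree = ntree, mtry = mtry,
                              min_node = min_node, max_depth = max_depth)),
            class = "rc_rf")
}

#' @export
predict.rc_rf <- function(object, newdata, ...) {
  x <- as_predictor_matrix(newdata, object$predictors)
  as.numeric(.forest_predict(object$trees, x))
}

#' Fit a gradient-boosted tree regressor
#'
#' Least-squares boosting of depth-limited CART trees with shrinkage.
#' Importance is the mean absolute SHAP value (path-dependent TreeSHAP)
#' over the training rows.
#'
#' @inheritParams fit_rf
#' @param nrounds boosting rounds.
#' @param eta shrinkage.
#' @param subsample row fraction per round (1 = deterministic given RNG).
#' @return object of class `rc_gbt`.
#' @export
fit_gbt <- function(x, y, nrounds = 300, eta = 0.1, max_depth = 3,
                    min_node = 10, subsample = 1) {
  x <- as_predictor_matrix(x)
  stopifnot(nrow(x) == length(y))
  fit <- .gbt_fit(x, as.numeric(y), as.integer(nrounds), eta,
                  as.integer(max_depth), as.integer(min_node), subsample)
  structure(list(model = fit, predictors = colnames(x), train_x = x,
                 hyper = list(nrounds = nrounds, eta = eta,
                              max_depth = max_depth, min_node = min_node,
                              subsample = subsample)),
            class = "rc_gbt")
}

#' @export
predict.rc_gbt <- function(object, newdata, ...) {
  x <- as_predictor_matrix(newdata, object$predictors)
  as.numeric(.gbt_predict(object$model, x))
}

#' SHAP values of a boosted-tree model
#'
#' Path-dependent TreeSHAP; row sums plus the model's expected value equal
#' the prediction exactly.
#'
#' @param object an `rc_gbt` fit.
#' @param newdata rows to explain (default: training rows).
#' @return matrix (rows x predictors) of SHAP values on the response scale.
#' @export
shap_values <- function(object, newdata = NULL) {
  stopifnot(inherits(object, "rc_gbt"))
  x <- if (is.null(newdata)) object$train_x
       else as_predictor_matrix(newdata, object$predictors)
  phi <- .gbt_shap(object$model, x)
  colnames(phi) <- object$predictors
  phi
}

#' Fit an RBF support-vector regressor
#'
#' Epsilon-insensitive SVR with a radial kernel, solved exactly by
#' coordinate descent on the box-constrained dual (bias folded into the
#' kernel). Predictors and response are internally standardized.
#'
#' @inheritParams fit_rf
#' @param cost box constraint C.
#' @param gamma RBF width; default `1 / p` on standardized predictors.
#' @param epsilon insensitivity half-width on the standardized response.
#' @param tol convergence tolerance on the max dual-coordinate change.
#' @param max_sweeps cap on coordinate-descent sweeps.
#' @return object of class `rc_svr`.
#' @export
fit_svr <- function(x, y, cost = 10, gamma = NULL, epsilon = 0.1,
                    tol = 1e-6, max_sweeps = 1000) {
  x <- as_predictor_matrix(x)
  stopifnot(nrow(x) == length(y))
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ym <- mean(y); ys <- sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  fit <- .svr_fit(xs, (y - ym) / ys, cost, gamma, epsilon, tol,
                  as.integer(max_sweeps))
  structure(list(beta = fit$beta, sweeps = fit$sweeps, train_x = xs,
                 center = ctr, scale = scl, y_mean = ym, y_sd = ys,
                 gamma = gamma, predictors = colnames(x),
                 hyper = list(cost = cost, gamma = gamma,
                              epsilon = epsilon)),
            class = "rc_svr")
}

#' @export
predict.rc_svr <- function(object, newdata, ...) {
  x <- as_predictor_matrix(newdata, object$predictors)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  f <- .svr_predict(object$train_x, object$beta, object$gamma, xs)
  as.numeric(f) * object$y_sd + object$y_mean
}

#' Per-algorithm predictor importance
#'
#' Dispatches to the importance measure native to each learner: mean
#' increase in OOB MSE for the forest, mean absolute SHAP for boosting,
#' and seeded permutation importance (increase in MSE on `x`/`y`) for the
#' SVR (or any model, when requested explicitly).
#'
#' @param object a fitted learner.
#' @param x,y data for permutation importance (required for `rc_svr`).
#' @param nperm permutations per predictor.
#' @return named numeric vector, one value per predictor.
#' @export
learner_importance <- function(object, x = NULL, y = NULL, nperm = 3) {
  UseMethod("learner_importance")
}

#' @export
learner_importance.rc_rf <- function(object, x = NULL, y = NULL, nperm = 3) {
  object$importance
}

#' @export
learner_importance.rc_gbt <- function(object, x = NULL, y = NULL, nperm = 3) {
  phi <- shap_values(object, x)
  colMeans(abs(phi))
}

#' @export
learner_importance.rc_svr <- function(object, x, y, nperm = 3) {
  permutation_importance(object, x, y, nperm = nperm)
}

#' Permutation importance for any fitted learner
#'
#' Mean increase in MSE over `nperm` within-column permutations, drawn from
#' the current RNG stream.
#'
#' @param object fitted learner with a `predict` method.
#' @param x predictor data; `y` response.
#' @param nperm permutations per predictor.
#' @return named numeric vector.
#' @export
permutation_importance <- function(object, x, y, nperm = 3) {
  x <- as_predictor_matrix(x, object$predictors)
  base <- mean((predict(object, x) - y)^2)
  imp <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    d <- 0
    for (k in seq_len(nperm)) {
      xp <- x
      xp[, j] <- x[sample.int(nrow(x)), j]
      d <- d + mean((predict(object, xp) - y)^2) - base
    }
    imp[j] <- d / nperm
  }
  setNames(imp, colnames(x))
}
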