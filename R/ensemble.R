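# Monthly three-learner ensembles for log CH4 concentration and log
# diffusive flux: correlation-filtered predictor selection, seeded CV
# hyperparameter tuning, window fits (a month and its two neighbours),
# LOOCV evaluation, importance fusion and partial dependence.

r_squared <- function(obs, pred) {
  if (sd(pred) == 0 || sd(obs) == 0) return(0)
  cor(obs, pred)^2
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

response_column <- function(response) {
  switch(response, ln_conc = "ch4_conc", ln_flux = "diff_flux",
         stop("unknown response: ", response))
}

# log-response vector from an observation table
response_vector <- function(observations, response) {
  col <- response_column(response)
  v <- observations[[col]]
  if (any(!is.finite(v) | v <= 0))
    stop(col, " must be > 0 for log-space modelling")
  log(v)
}

#' Default modeling predictor set (21 variables)
#'
#' The 16 terrestrial predictors plus the 5 aquatic predictors.
#' @param extra the two config-declared terrestrial names.
#' @return character vector of length 21.
#' @export
default_predictors <- function(extra = c("ndvi", "wetland_fraction")) {
  c(terrestrial_predictors(extra), aquatic_predictors())
}

# Decide (once, on the supplied data) which predictors are skewed enough to
# store post-log-transform; returns per-predictor transform flag + offset.
predictor_transforms <- function(data, predictors, ...) {
  out <- list()
  for (p in predictors) {
    v <- data[[p]]
    if (any(v < 0, na.rm = TRUE)) {
      # signed predictors (e.g. air temperature) cannot take the log branch
      out[[p]] <- list(transform = "none", offset = 0)
    } else {
      nt <- normality_transform(v, ...)
      out[[p]] <- list(transform = nt$transform, offset = nt$offset)
    }
  }
  out
}

apply_predictor_transforms <- function(data, transforms) {
  for (p in names(transforms)) {
    tr <- transforms[[p]]
    if (tr$transform == "log") {
      v <- data[[p]]
      if (any(v < 0, na.rm = TRUE))
        stop("negative values in log-flagged predictor ", p)
      data[[p]] <- log(v + tr$offset)
    }
  }
  data
}

#' Correlation-filtered predictor selection
#'
#' Keeps candidates whose absolute Pearson correlation with the log
#' response exceeds `threshold`, plus a mechanistic keep-list retained
#' regardless of correlation strength.
#'
#' @param observations observation table.
#' @param response `"ln_conc"` or `"ln_flux"`.
#' @param candidates candidate predictor columns.
#' @param threshold |r| cutoff.
#' @param keep mechanistic keep-list.
#' @return `data.frame` report: predictor, r, selected, reason.
#' @export
select_predictors <- function(observations, response = "ln_flux",
                              candidates = default_predictors(),
                              threshold = 0.1,
                              keep = c("precipitation", "gpp", "npp",
                                       "soil_respiration")) {
  if (!length(candidates)) stop("empty candidate set")
  missing <- setdiff(candidates, names(observations))
  if (length(missing))
    stop("candidates absent from table: ", paste(missing, collapse = ", "))
  y <- response_vector(observations, response)
  trans <- predictor_transforms(observations, candidates)
  dat <- apply_predictor_transforms(observations, trans)
  r <- vapply(candidates, function(p)
    suppressWarnings(cor(y, dat[[p]], use = "complete.obs")), numeric(1))
  r[is.na(r)] <- 0
  selected <- abs(r) > threshold | candidates %in% keep
  reason <- ifelse(abs(r) > threshold, "correlation",
                   ifelse(candidates %in% keep, "mechanistic", "dropped"))
  data.frame(predictor = candidates, r = unname(r), selected = selected,
             reason = reason, stringsAsFactors = FALSE)
}

#' Default hyperparameter grids
#'
#' Small grids for desk-scale tests; `scale = "full"` widens them.
#'
#' @param scale `"test"` or `"full"`.
#' @return named list of data-frame grids for `rf`, `gbt`, `svr`.
#' @export
default_grids <- function(scale = c("test", "full")) {
  scale <- match.arg(scale)
  if (scale == "test") {
    list(rf = expand.grid(ntree = 60, mtry = NA, min_node = 5,
                          max_depth = 0),
         gbt = expand.grid(nrounds = 150, eta = 0.1, max_depth = 3,
                           min_node = 10),
         svr = expand.grid(cost = 10, gamma = NA, epsilon = 0.1))
  } else {
    list(rf = expand.grid(ntree = c(200, 500), mtry = c(NA, 7),
                          min_node = c(5, 10), max_depth = 0),
         gbt = expand.grid(nrounds = c(300, 600), eta = c(0.05, 0.1),
                           max_depth = c(3, 5), min_node = 10),
         svr = expand.grid(cost = c(1, 10, 100), gamma = NA,
                           epsilon = c(0.05, 0.1)))
  }
}

fit_learner <- function(kind, x, y, hyper) {
  hyper <- as.list(hyper)
  hyper <- hyper[!vapply(hyper, function(v) is.na(v), logical(1))]
  switch(kind,
    rf = do.call(fit_rf, c(list(x = x, y = y), hyper)),
    gbt = do.call(fit_gbt, c(list(x = x, y = y), hyper)),
    svr = do.call(fit_svr, c(list(x = x, y = y), hyper)),
    stop("unknown learner kind: ", kind))
}

#' Grid search by k-fold cross-validation
#'
#' Evaluates every grid row by seeded k-fold CV and returns the row
#' minimizing the mean squared residual; ties break in first-in-grid order.
#'
#' @param x predictor matrix or data frame; `y` response.
#' @param kind learner kind: `"rf"`, `"gbt"` or `"svr"`.
#' @param grid data frame of hyperparameter combinations.
#' @param folds number of CV folds.
#' @param seed RNG seed for fold assignment and stochastic fits.
#' @return list with `best` (named list), `cv_mse` per grid row, `grid`.
#' @export
tune_hyperparameters <- function(x, y, kind, grid, folds = 10, seed = 1L) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  x <- as_predictor_matrix(x)
  n <- nrow(x)
  if (n < folds) stop("n (", n, ") below number of folds (", folds, ")")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(folds), n))
    cv_mse <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      sse <- 0
      for (k in seq_len(folds)) {
        tr <- fold != k
        fit <- fit_learner(kind, x[tr, , drop = FALSE], y[tr], grid[g, ])
        pr <- predict(fit, x[!tr, , drop = FALSE])
        sse <- sse + sum((pr - y[!tr])^2)
      }
      cv_mse[g] <- sse / n
    }
    best <- as.list(grid[which.min(cv_mse), ])
    best <- best[!vapply(best, is.na, logical(1))]
    list(best = best, cv_mse = cv_mse, grid = grid)
  })
}

# calendar window: the month and its two adjacent months, wrapping the year
month_window <- function(month) {
  stopifnot(month %in% 1:12)
  ((c(month - 1L, month, month + 1L) - 1L) %% 12L) + 1L
}

#' Fit a monthly three-learner ensemble
#'
#' Trains a forest, a boosted-tree model and an SVR on the observations of
#' a calendar month and its two adjacent months (wrapping across the year
#' boundary), using a seeded 70/30 train/test split; all three learners see
#' identical training rows. Skew-flagged predictors are stored
#' post-log-transform; the transform decisions travel with the ensemble so
#' prediction-time tables are transformed identically.
#'
#' @param observations observation table.
#' @param month focal calendar month (1-12).
#' @param response `"ln_conc"` or `"ln_flux"`.
#' @param predictors predictor columns (default the 21-variable set).
#' @param hyper named list of per-learner hyperparameter lists (e.g. from
#'   [tune_hyperparameters()]); defaults to the first row of the test grids.
#' @param tune if `TRUE`, tune each learner on the training split first.
#' @param grids grids for tuning.
#' @param train_frac training fraction of the window.
#' @param min_n minimum windowed observation count.
#' @param seed RNG seed (split and stochastic fits).
#' @return object of class `monthly_ensemble`.
#' @export
fit_monthly_ensemble <- function(observations, month,
                                 response = c("ln_flux", "ln_conc"),
                                 predictors = NULL, hyper = NULL,
                                 tune = FALSE, grids = default_grids(),
                                 train_frac = 0.7, min_n = 30, seed = 1L) {
  response <- match.arg(response)
  if (is.null(predictors))
    predictors <- intersect(default_predictors(), names(observations))
  win <- month_window(month)
  idx <- which(observations$month %in% win)
  if (length(idx) < min_n)
    stop("month ", month, ": windowed observation count ", length(idx),
         " below minimum ", min_n)
  dat <- observations[idx, , drop = FALSE]
  y <- response_vector(dat, response)
  trans <- predictor_transforms(dat, predictors)
  xdat <- apply_predictor_transforms(dat, trans)
  x <- as_predictor_matrix(xdat, predictors)

  with_seed(seed, {
    ntr <- max(2L, floor(train_frac * nrow(x)))
    tr_idx <- sort(sample.int(nrow(x), ntr))
    te_idx <- setdiff(seq_len(nrow(x)), tr_idx)
    xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    xte <- x[te_idx, , drop = FALSE]; yte <- y[te_idx]

    kinds <- c("rf", "gbt", "svr")
    if (is.null(hyper)) {
      hyper <- lapply(kinds, function(k) {
        h <- as.list(grids[[k]][1, ])
        h[!vapply(h, is.na, logical(1))]
      })
      names(hyper) <- kinds
    }
    if (tune) {
      for (k in kinds)
        hyper[[k]] <- tune_hyperparameters(xtr, ytr, k, grids[[k]],
                                           folds = min(10, nrow(xtr)),
                                           seed = seed)$best
    }
    fits <- lapply(kinds, function(k) fit_learner(k, xtr, ytr, hyper[[k]]))
    names(fits) <- kinds

    preds_te <- vapply(fits, function(f) predict(f, xte), numeric(length(yte)))
    metrics <- data.frame(
      learner = c(kinds, "ensemble"),
      r_squared = c(vapply(kinds, function(k)
        r_squared(yte, preds_te[, k]), numeric(1)),
        r_squared(yte, rowMeans(preds_te))),
      rmse = c(vapply(kinds, function(k)
        rmse(yte, preds_te[, k]), numeric(1)),
        rmse(yte, rowMeans(preds_te))),
      stringsAsFactors = FALSE)

    importance <- list(
      rf = learner_importance(fits$rf),
      gbt = learner_importance(fits$gbt),
      svr = learner_importance(fits$svr, xtr, ytr))

    # Duan smearing factor from ensemble-mean training residuals
    res_tr <- ytr - rowMeans(vapply(fits, function(f) predict(f, xtr),
                                    numeric(length(ytr))))
    structure(list(month = month, response = response, window = win,
                   predictors = predictors, transforms = trans,
                   fits = fits, hyper = hyper,
                   train_idx = idx[tr_idx], test_idx = idx[te_idx],
                   importance = importance, metrics = metrics,
                   smearing_factor = mean(exp(res_tr)),
                   train_x = xtr, train_y = ytr),
              class = "monthly_ensemble")
  })
}

#' Predict from a monthly ensemble
#'
#' Averages the three learners' log-scale predictions and, for
#' `type = "natural"`, exponentiates the mean (optionally applying the Duan
#' smearing factor estimated on the training residuals).
#'
#' @param ensemble a `monthly_ensemble`.
#' @param newdata table carrying all ensemble predictors on their original
#'   (pre-transform) scales.
#' @param type `"natural"` (back-transformed) or `"log"`.
#' @param smearing apply the smearing retransformation correction.
#' @param members if `TRUE`, also return the per-learner predictions.
#' @return numeric vector, or a list with `mean` and `members`.
#' @export
ensemble_predict <- function(ensemble, newdata,
                             type = c("natural", "log"),
                             smearing = FALSE, members = FALSE) {
  type <- match.arg(type)
  stopifnot(inherits(ensemble, "monthly_ensemble"))
  missing <- setdiff(ensemble$predictors, names(newdata))
  if (length(missing))
    stop("newdata missing predictors: ", paste(missing, collapse = ", "))
  xdat <- apply_predictor_transforms(newdata, ensemble$transforms)
  x <- as_predictor_matrix(xdat, ensemble$predictors)
  pm <- vapply(ensemble$fits, function(f) predict(f, x),
               numeric(nrow(x)))
  if (nrow(x) == 1L) pm <- matrix(pm, nrow = 1,
                                  dimnames = list(NULL, names(ensemble$fits)))
  out <- rowMeans(pm)
  if (type == "natural") {
    fac <- if (smearing) ensemble$smearing_factor else 1
    out <- exp(out) * fac
    pm <- exp(pm) * fac
  }
  if (members) list(mean = out, members = pm) else out
}

#' Leave-one-out cross-validation of the ensemble
#'
#' Performs exactly n fits (each on n-1 rows), stacking the held-out
#' ensemble predictions against the observations. For n above `cap` a
#' fixed-seed subsample of size `cap` is used instead, with a warning,
#' keeping desk-scale runtimes bounded.
#'
#' @param observations observation table.
#' @param response `"ln_conc"` or `"ln_flux"`.
#' @param predictors predictor columns.
#' @param hyper per-learner hyperparameter lists (default test grids).
#' @param cap maximum number of LOOCV fits before subsampling.
#' @param seed RNG seed (subsample and stochastic fits).
#' @return list: `r_squared`, `rmse`, `n_fits`, `predictions`, `observed`.
#' @export
loocv_evaluate <- function(observations, response = "ln_flux",
                           predictors = NULL, hyper = NULL,
                           cap = 200L, seed = 1L) {
  if (is.null(predictors))
    predictors <- intersect(default_predictors(), names(observations))
  if (nrow(observations) < 3) stop("need at least 3 observations")
  if (nrow(observations) > cap) {
    warning("LOOCV capped: subsampling ", cap, " of ",
            nrow(observations), " rows")
    observations <- with_seed(seed + 1L,
      observations[sort(sample.int(nrow(observations), cap)), , drop = FALSE])
  }
  y <- response_vector(observations, response)
  trans <- predictor_transforms(observations, predictors)
  xdat <- apply_predictor_transforms(observations, trans)
  x <- as_predictor_matrix(xdat, predictors)
  kinds <- c("rf", "gbt", "svr")
  if (is.null(hyper)) {
    g <- default_grids()
    hyper <- lapply(kinds, function(k) {
      h <- as.list(g[[k]][1, ]); h[!vapply(h, is.na, logical(1))]
    })
    names(hyper) <- kinds
  }
  n <- nrow(x)
  preds <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      xt <- x[-i, , drop = FALSE]; yt <- y[-i]
      p3 <- vapply(kinds, function(k)
        predict(fit_learner(k, xt, yt, hyper[[k]]), x[i, , drop = FALSE]),
        numeric(1))
      preds[i] <- mean(p3)
    }
  })
  list(r_squared = r_squared(y, preds), rmse = rmse(y, preds),
       n_fits = n, predictions = preds, observed = y)
}

#' Fuse per-algorithm importances into a 0-1 ranking
#'
#' Min-max normalizes each algorithm's raw importance vector to [0, 1],
#' averages them with equal weight, and ranks descending; the top
#' `top` predictors are flagged. Invariant to positive affine rescaling of
#' any single algorithm's raw vector.
#'
#' @param ensemble a `monthly_ensemble` (or a named list of raw importance
#'   vectors over identical predictors).
#' @param top number of top predictors to flag.
#' @return `data.frame`: predictor, per-algorithm normalized scores, fused
#'   score, rank, top flag (ordered by rank).
#' @export
fuse_importance <- function(ensemble, top = 15) {
  raw <- if (inherits(ensemble, "monthly_ensemble")) ensemble$importance
         else ensemble
  if (is.null(raw) || !length(raw)) stop("no importance vectors available")
  preds <- names(raw[[1]])
  norm <- lapply(raw, function(v) {
    stopifnot(identical(names(v), preds))
    rng <- range(v)
    if (diff(rng) == 0) return(setNames(rep(0, length(v)), preds))
    (v - rng[1]) / diff(rng)
  })
  fused <- Reduce(`+`, norm) / length(norm)
  out <- data.frame(predictor = preds, stringsAsFactors = FALSE)
  for (k in names(norm)) out[[paste0("score_", k)]] <- unname(norm[[k]])
  out$fused <- unname(fused)
  out <- out[order(-out$fused), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top
  rownames(out) <- NULL
  out
}

#' Nutrient ablation and swap comparison
#'
#' Compares held-out ensemble R-squared for three predictor sets on one
#' identical seeded split: the full set, the set without the four nutrient
#' concentrations, and a swap set in which the four most influential
#' non-nutrient predictors of the full fit are replaced by the nutrients
#' (holding predictor count fixed).
#'
#' @param observations observation table.
#' @param response `"ln_conc"` or `"ln_flux"`.
#' @param predictors full predictor set.
#' @param nutrients the nutrient predictor names.
#' @param hyper per-learner hyperparameters; `seed` split/fit seed;
#'   `train_frac` training fraction.
#' @return list with `r_squared` (named: full, no_nutrient, swapped),
#'   `delta_r2` (full minus no_nutrient) and `swapped_out` predictor names.
#' @export
ablation_compare <- function(observations, response = "ln_flux",
                             predictors = NULL,
                             nutrients = c("TP", "NH4N", "TN", "NO3N"),
                             hyper = NULL, train_frac = 0.7, seed = 1L) {
  if (is.null(predictors))
    predictors <- intersect(default_predictors(), names(observations))
  if (!all(nutrients %in% predictors))
    stop("nutrient columns absent from predictor set")
  y <- response_vector(observations, response)
  trans <- predictor_transforms(observations, predictors)
  xdat <- apply_predictor_transforms(observations, trans)
  x <- as_predictor_matrix(xdat, predictors)
  kinds <- c("rf", "gbt", "svr")
  if (is.null(hyper)) {
    g <- default_grids()
    hyper <- lapply(kinds, function(k) {
      h <- as.list(g[[k]][1, ]); h[!vapply(h, is.na, logical(1))]
    })
    names(hyper) <- kinds
  }
  eval_set <- function(cols, tr_idx) {
    xt <- x[tr_idx, cols, drop = FALSE]
    xe <- x[-tr_idx, cols, drop = FALSE]
    pm <- vapply(kinds, function(k)
      predict(fit_learner(k, xt, y[tr_idx], hyper[[k]]), xe),
      numeric(nrow(xe)))
    r_squared(y[-tr_idx], rowMeans(pm))
  }
  with_seed(seed, {
    tr_idx <- sort(sample.int(nrow(x), max(2L, floor(train_frac * nrow(x)))))
    full <- eval_set(predictors, tr_idx)
    no_nut <- eval_set(setdiff(predictors, nutrients), tr_idx)
    # rank non-nutrient predictors by fused importance of the full fit
    fits <- lapply(kinds, function(k)
      fit_learner(k, x[tr_idx, , drop = FALSE], y[tr_idx], hyper[[k]]))
    names(fits) <- kinds
    imp <- list(rf = learner_importance(fits$rf),
                gbt = learner_importance(fits$gbt),
                svr = learner_importance(fits$svr, x[tr_idx, , drop = FALSE],
                                         y[tr_idx]))
    fused <- fuse_importance(imp, top = length(predictors))
    top_watershed <- head(
      fused$predictor[!fused$predictor %in% nutrients], 4)
    swapped_set <- union(setdiff(setdiff(predictors, nutrients),
                                 top_watershed), nutrients)
    swapped <- eval_set(swapped_set, tr_idx)
    list(r_squared = c(full = full, no_nutrient = no_nut, swapped = swapped),
         delta_r2 = full - no_nut, swapped_out = top_watershed)
  })
}

#' Partial dependence of the ensemble on one predictor
#'
#' Mean ensemble prediction over a reference table with the predictor
#' clamped to each grid value (grid on the original, pre-transform scale).
#'
#' @param ensemble a `monthly_ensemble`.
#' @param predictor predictor name.
#' @param grid numeric grid of clamp values (non-empty).
#' @param data reference table; defaults to the ensemble's training rows
#'   (back on the stored transformed scale, so `data` is recommended for
#'   interpretability).
#' @param type `"log"` or `"natural"` prediction scale.
#' @return `data.frame` with `value` and `yhat`.
#' @export
partial_dependence <- function(ensemble, predictor, grid, data = NULL,
                               type = c("log", "natural")) {
  type <- match.arg(type)
  stopifnot(inherits(ensemble, "monthly_ensemble"))
  if (!length(grid)) stop("empty grid")
  if (!predictor %in% ensemble$predictors)
    stop("predictor not in model: ", predictor)
  if (is.null(data)) {
    # training matrix is already transformed; invert is not needed because
    # we clamp after transform in that case
    x <- ensemble$train_x
    tr <- ensemble$transforms[[predictor]]
    yhat <- vapply(grid, function(v) {
      vv <- if (tr$transform == "log") log(v + tr$offset) else v
      xc <- x
      xc[, predictor] <- vv
      pm <- vapply(ensemble$fits, function(f) predict(f, xc),
                   numeric(nrow(xc)))
      m <- mean(rowMeans(pm))
      if (type == "natural") exp(m) else m
    }, numeric(1))
  } else {
    yhat <- vapply(grid, function(v) {
      d <- data
      d[[predictor]] <- v
      mean(ensemble_predict(ensemble, d, type = type))
    }, numeric(1))
  }
  data.frame(value = grid, yhat = yhat)
}
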