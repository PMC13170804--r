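test_that("predictor selection keeps signal and mechanistic candidates", {
  obs <- simulate_observations(2000, tp_single(seed = 31, noise = 0.3))
  set.seed(31)
  obs$pure_noise <- rnorm(nrow(obs))
  rep <- select_predictors(obs, "ln_flux",
                           candidates = c("TP", "gpp", "pure_noise"),
                           threshold = 0.1,
                           keep = c("gpp"))
  rep <- setNames(split(rep, rep$predictor), rep$predictor)
  expect_true(rep$TP$selected)
  expect_equal(rep$TP$reason, "correlation")
  expect_true(rep$gpp$selected)
  expect_equal(rep$gpp$reason, "mechanistic")
  expect_false(rep$pure_noise$selected)
  expect_error(select_predictors(obs, candidates = character(0)), "empty")
  expect_error(select_predictors(obs, candidates = "nope"), "absent")
})

test_that("a predictor identical to the response is kept", {
  obs <- simulate_observations(100, tp_single(seed = 32))
  obs$self <- log(obs$diff_flux)
  rep <- select_predictors(obs, "ln_flux", candidates = "self",
                           keep = character(0))
  expect_true(rep$selected)
  expect_equal(abs(rep$r), 1, tolerance = 1e-9)
})

test_that("tuning picks the singleton and is deterministic", {
  d <- local({
    set.seed(33)
    x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
    list(x = x, y = x[, 1] + rnorm(200, 0, 0.2))
  })
  single <- expand.grid(ntree = 25, min_node = 5)
  out <- tune_hyperparameters(d$x, d$y, "rf", single, folds = 5, seed = 2)
  expect_equal(out$best, list(ntree = 25, min_node = 5))
  grid <- expand.grid(cost = c(0.01, 10), epsilon = 0.1)
  t1 <- tune_hyperparameters(d$x, d$y, "svr", grid, folds = 5, seed = 2)
  t2 <- tune_hyperparameters(d$x, d$y, "svr", grid, folds = 5, seed = 2)
  expect_identical(t1, t2)
  expect_error(tune_hyperparameters(d$x[1:4, ], d$y[1:4], "rf", single,
                                    folds = 10), "below number of folds")
  expect_error(tune_hyperparameters(d$x, d$y, "rf", single[0, , drop = FALSE]),
               "empty")
})

test_that("CV tuning prefers the better-specified setting", {
  set.seed(34)
  x <- matrix(rnorm(400 * 2), 400, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1.2 * x[, 1] + rnorm(400, 0, 0.1)
  # boosting with enough rounds beats a crippled 1-round configuration
  grid <- expand.grid(nrounds = c(1, 150), eta = 0.1, max_depth = 3,
                      min_node = 10)
  out <- tune_hyperparameters(x, y, "gbt", grid, folds = 5, seed = 3)
  expect_equal(out$best$nrounds, 150)
  expect_lt(out$cv_mse[2], out$cv_mse[1])
})

test_that("monthly windows include the two adjacent months and wrap", {
  expect_equal(riverch4:::month_window(1), c(12, 1, 2))
  expect_equal(riverch4:::month_window(6), c(5, 6, 7))
  expect_equal(riverch4:::month_window(12), c(11, 12, 1))
  obs <- simulate_observations(600, tp_single(seed = 35))
  ens <- fit_monthly_ensemble(obs, 1, "ln_flux", hyper = fast_hyper(),
                              min_n = 20, seed = 4)
  used <- sort(unique(obs$month[c(ens$train_idx, ens$test_idx)]))
  expect_equal(used, c(1, 2, 12))
  expect_error(fit_monthly_ensemble(obs[obs$month == 5, ][1:5, ], 6,
                                    "ln_flux", min_n = 30),
               "month 6")
})

test_that("the 70/30 split is seeded and learners share training rows", {
  obs <- simulate_observations(500, tp_single(seed = 36))
  e1 <- fit_monthly_ensemble(obs, 3, "ln_flux", hyper = fast_hyper(),
                             min_n = 20, seed = 5)
  e2 <- fit_monthly_ensemble(obs, 3, "ln_flux", hyper = fast_hyper(),
                             min_n = 20, seed = 5)
  expect_identical(e1$train_idx, e2$train_idx)
  expect_identical(predict(e1$fits$rf, e1$train_x),
                   predict(e2$fits$rf, e2$train_x))
  n_win <- length(e1$train_idx) + length(e1$test_idx)
  expect_equal(length(e1$train_idx), floor(0.7 * n_win))
})

test_that("ensemble averaging happens in log space", {
  ens <- const_ensemble(c(1, 2, 3))
  nd <- data.frame(v1 = 0.5, v2 = 0.5, v3 = 0.5)
  expect_equal(ensemble_predict(ens, nd, type = "log"), 2, tolerance = 1e-6)
  expect_equal(ensemble_predict(ens, nd), exp(2), tolerance = 1e-5)
  same <- const_ensemble(c(1.5, 1.5, 1.5))
  expect_equal(ensemble_predict(same, nd, type = "log"), 1.5,
               tolerance = 1e-6)
  expect_error(ensemble_predict(ens, data.frame(v1 = 1)),
               "missing predictors: v2, v3")
})

test_that("tree members are monotone along the dominant nutrient ramp", {
  obs <- simulate_observations(1500, tp_single(seed = 37, beta = 0.8,
                                               noise = 0.2))
  ens <- fit_monthly_ensemble(obs, 6, "ln_flux",
                              predictors = c("TP", "NH4N", "water_temp"),
                              hyper = fast_hyper(), min_n = 50, seed = 6)
  base <- obs[obs$month %in% 5:7, ][1:40, c("TP", "NH4N", "water_temp")]
  ramp <- quantile(obs$TP, c(0.1, 0.3, 0.5, 0.7, 0.9))
  for (learner in c("rf", "gbt")) {
    means <- vapply(ramp, function(v) {
      d <- base; d$TP <- v
      x <- riverch4:::apply_predictor_transforms(d, ens$transforms)
      mean(predict(ens$fits[[learner]],
                   riverch4:::as_predictor_matrix(x, ens$predictors)))
    }, numeric(1))
    expect_true(all(diff(means) > -1e-8), label = learner)
  }
})

test_that("LOOCV performs exactly n fits and nails noiseless data", {
  obs <- simulate_observations(40, tp_single(seed = 38, noise = 0))
  out <- loocv_evaluate(obs, "ln_flux", predictors = c("TP", "NH4N"),
                        hyper = list(rf = list(ntree = 40, mtry = 2,
                                               min_node = 2),
                                     gbt = list(nrounds = 200, eta = 0.2,
                                                max_depth = 4, min_node = 2),
                                     svr = list(cost = 100,
                                                epsilon = 0.001)),
                        cap = 100, seed = 7)
  expect_equal(out$n_fits, 40)
  expect_gt(out$r_squared, 0.95)
  expect_error(loocv_evaluate(obs[1:2, ], "ln_flux"), "at least 3")
  expect_warning(
    loocv_evaluate(obs, "ln_flux", predictors = c("TP", "NH4N"),
                   hyper = list(rf = list(ntree = 5),
                                gbt = list(nrounds = 5),
                                svr = list()),
                   cap = 10, seed = 7),
    "capped")
})

test_that("LOOCV R2 is near zero when the response is independent", {
  obs <- simulate_observations(80, tp_single(seed = 39, beta = 0,
                                             noise = 0.5))
  out <- loocv_evaluate(obs, "ln_flux", predictors = c("TP", "NH4N"),
                        hyper = fast_hyper(), cap = 100, seed = 8)
  expect_lt(out$r_squared, 0.1)
})

test_that("importance fusion normalizes, ranks, and is affine-invariant", {
  raw <- list(rf = c(a = 5, b = 1, c = 0),
              gbt = c(a = 0.9, b = 0.2, c = 0.1),
              svr = c(a = 30, b = 30, c = 10))
  fused <- fuse_importance(raw, top = 2)
  expect_equal(fused$predictor[1], "a")
  expect_equal(fused$fused[fused$predictor == "a"], 1)
  expect_true(all(fused$fused >= 0 & fused$fused <= 1))
  expect_equal(sum(fused$top), 2)
  # positive affine rescaling of one algorithm leaves the fusion unchanged
  raw2 <- raw
  raw2$gbt <- 7 * raw$gbt + 3
  expect_equal(fuse_importance(raw2, top = 2), fused)
  expect_error(fuse_importance(list()), "no importance")
})

test_that("a predictor carrying all signal gets fused score 1", {
  raw <- list(rf = c(s = 10, n1 = 0, n2 = 0),
              gbt = c(s = 2, n1 = 0, n2 = 0),
              svr = c(s = 0.4, n1 = 0, n2 = 0))
  fused <- fuse_importance(raw, top = 1)
  expect_equal(fused$fused, c(1, 0, 0))
  expect_equal(fused$rank[fused$predictor == "s"], 1)
})

test_that("nutrient ablation detects a nutrient-only signal", {
  obs <- simulate_observations(700, tp_single(seed = 40, beta = 0.8,
                                              noise = 0.2))
  preds <- c("TP", "NH4N", "TN", "NO3N", "slope", "elevation", "gpp",
             "precipitation", "water_temp")
  out <- ablation_compare(obs, "ln_flux", predictors = preds,
                          hyper = fast_hyper(), seed = 9)
  expect_gt(out$r_squared[["full"]], 0.6)
  expect_lt(out$r_squared[["no_nutrient"]], 0.25)
  expect_gt(out$delta_r2, 0.4)
  expect_equal(length(out$swapped_out), 4)
  out2 <- ablation_compare(obs, "ln_flux", predictors = preds,
                           hyper = fast_hyper(), seed = 9)
  expect_identical(out, out2)
  expect_error(ablation_compare(obs, "ln_flux",
                                predictors = c("slope", "gpp")),
               "nutrient columns absent")
})

test_that("partial dependence is flat for constant models and linear for
          linear signal", {
  ens <- const_ensemble(c(2, 2, 2))
  pd <- partial_dependence(ens, "v1", grid = c(0.1, 0.5, 0.9))
  expect_lt(diff(range(pd$yhat)), 1e-6)
  pd1 <- partial_dependence(ens, "v1", grid = 0.5)
  expect_equal(nrow(pd1), 1)
  expect_error(partial_dependence(ens, "v1", numeric(0)), "empty grid")
  expect_error(partial_dependence(ens, "zz", 1), "not in model")

  obs <- simulate_observations(1200, tp_single(seed = 41, beta = 0.6,
                                               noise = 0.2))
  mens <- fit_monthly_ensemble(obs, 6, "ln_flux",
                               predictors = c("TP", "NH4N", "water_temp"),
                               hyper = fast_hyper(), min_n = 50, seed = 10)
  grid <- exp(seq(log(quantile(obs$TP, 0.15)), log(quantile(obs$TP, 0.85)),
                  length.out = 6))
  pd <- partial_dependence(mens, "TP", grid)
  fitlin <- lm(pd$yhat ~ log(pd$value))
  expect_gt(summary(fitlin)$r.squared, 0.9)
  expect_gt(coef(fitlin)[2], 0)
})
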