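# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

# truth params with a single active elasticity (TP), everything else off
tp_single <- function(seed = 1L, beta = 0.5, noise = 0.3) {
  truth_params(seed = seed, beta_logTP = beta, beta_logNH4 = 0,
               beta_logTN = 0, beta_logNO3 = 0, beta_temp = 0,
               terrestrial_betas = c(gpp = 0), noise_sd = noise,
               conc_noise_sd = noise)
}

# small world used by upscaling / scenario tests
tiny_world <- function(seed = 3L, n_cells = 4, reaches_per_cell = 3) {
  p <- truth_params(seed = seed)
  net <- generate_network(n_cells, reaches_per_cell, p)
  list(params = p, reaches = net$reaches, cells = net$cells)
}

# --- Wilcoxon oracle: full enumeration over rank assignments ---------------
# two-sided p of the Mann-Whitney U statistic by enumerating all C(n+m, n)
# ways the pooled ranks can be assigned to sample a (no ties assumed)
wilcox_enum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ranks <- seq_len(n + m)
  us <- apply(combos, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- TreeSHAP oracle: brute-force Shapley of the tree expectation ----------
# path-dependent expectation: descend by x for features in S, otherwise
# average children weighted by training cover
tree_expect <- function(tr, x, S) {
  rec <- function(i) {
    f <- tr$feature[i]
    if (f < 0) return(tr$value[i])
    if ((f + 1) %in% S) {
      if (x[f + 1] <= tr$thr[i]) rec(tr$left[i] + 1) else rec(tr$right[i] + 1)
    } else {
      (tr$cover[tr$left[i] + 1] * rec(tr$left[i] + 1) +
         tr$cover[tr$right[i] + 1] * rec(tr$right[i] + 1)) / tr$cover[i]
    }
  }
  rec(1)
}

brute_shap <- function(tr, x, p) {
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (mask in 0:(2^length(others) - 1)) {
      S <- others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0]
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[j] <- phi[j] +
        w * (tree_expect(tr, x, c(S, j)) - tree_expect(tr, x, S))
    }
  }
  phi
}

# --- SVR oracle: the same dual solved by quadprog --------------------------
svr_qp_oracle <- function(fit, y, epsilon, cost) {
  xs <- fit$train_x
  ys <- (y - fit$y_mean) / fit$y_sd
  n <- length(ys)
  K <- exp(-fit$gamma * as.matrix(dist(xs))^2) + 1
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  d <- c(ys - epsilon, -ys - epsilon)
  A <- cbind(diag(2 * n), -diag(2 * n))
  b0 <- c(rep(0, 2 * n), rep(-cost, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0)
  sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
}

# ensemble whose three members predict the constants in `vals`
const_ensemble <- function(vals, p = 3) {
  x <- matrix(seq_len(20 * p) / (20 * p), 20, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  set.seed(99)
  fits <- list(rf = fit_rf(x, rep(vals[1], 20), ntree = 5),
               gbt = fit_gbt(x, rep(vals[2], 20), nrounds = 5),
               svr = fit_svr(x, rep(vals[3], 20)))
  trans <- setNames(rep(list(list(transform = "none", offset = 0)), p),
                    colnames(x))
  structure(list(fits = fits, predictors = colnames(x), transforms = trans,
                 smearing_factor = 1, month = 1, response = "ln_flux",
                 train_x = x),
            class = "monthly_ensemble")
}

# small per-learner hyperparameters reused across tests
fast_hyper <- function() {
  list(rf = list(ntree = 60, min_node = 5),
       gbt = list(nrounds = 150, eta = 0.1, max_depth = 3, min_node = 10),
       svr = list(cost = 10, epsilon = 0.1))
}
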