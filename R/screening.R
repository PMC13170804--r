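# Driver screening: Shapiro-Wilk-gated log transforms, Z-score
# standardized bivariate regressions, subgroup and population-density
# gradient analyses, and Wilcoxon rank-sum group comparisons.

#' Normality-gated log transform
#'
#' Assesses normality with the Shapiro-Wilk test and natural-log transforms
#' the vector when p < `alpha`. For samples larger than `max_n` the test is
#' run on a fixed-seed subsample (the test statistic is defined for limited
#' n). Zeros under the log branch are offset by half the smallest positive
#' value (policy recorded in the result); negative values under the log
#' branch are an error.
#'
#' @param values numeric vector, n >= 3 after NA removal.
#' @param alpha significance level for the Shapiro-Wilk test.
#' @param max_n cap on the sample size passed to the test.
#' @param subsample_seed seed for the capped subsample.
#' @return list with `values` (transformed, NAs preserved in place),
#'   `transform` ("none" or "log"), `offset`, and `shapiro_p`.
#' @export
normality_transform <- function(values, alpha = 0.05, max_n = 5000,
                                subsample_seed = 1L) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 3) stop("need at least 3 non-missing values")
  if (sd(v) == 0)
    return(list(values = values, transform = "none", offset = 0,
                shapiro_p = NA_real_))
  test_v <- if (length(v) > max_n)
    with_seed(subsample_seed, sample(v, max_n)) else v
  p <- shapiro.test(test_v)$p.value
  if (p >= alpha)
    return(list(values = values, transform = "none", offset = 0,
                shapiro_p = p))
  if (any(v < 0)) stop("negative values cannot be log-transformed")
  offset <- 0
  if (any(v == 0)) {
    pos <- v[v > 0]
    if (!length(pos)) stop("all values zero; cannot log-transform")
    offset <- min(pos) / 2
  }
  out <- values
  out[ok] <- log(v + offset)
  list(values = out, transform = "log", offset = offset, shapiro_p = p)
}

#' Z-score standardization
#'
#' @param values numeric vector, n >= 2, non-constant.
#' @return vector with sample mean 0 and sample sd 1.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("constant vector cannot be Z-scored")
  (values - mean(values)) / s
}

#' Standardized regression coefficient between two variables
#'
#' Slope of Z-scored `y` on Z-scored `x` after pairwise removal of missing
#' values, with the two-sided p-value of the regression slope. In this
#' bivariate form the coefficient equals the Pearson correlation.
#'
#' @param y,x numeric vectors of equal length.
#' @param response,predictor,subgroup labels carried into the record.
#' @return one-row `data.frame`: response, predictor, subgroup, coefficient,
#'   n_used, p_value.
#' @export
standardized_coefficient <- function(y, x, response = "y", predictor = "x",
                                     subgroup = "global") {
  stopifnot(length(y) == length(x))
  ok <- complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need at least 3 complete pairs")
  fit <- lm(zscore(y) ~ zscore(x))
  # perfect fits (|r| = 1) are legitimate inputs; silence lm's advisory
  sm <- suppressWarnings(summary(fit))$coefficients
  data.frame(response = response, predictor = predictor, subgroup = subgroup,
             coefficient = unname(coef(fit)[2]), n_used = length(y),
             p_value = unname(sm[2, 4]), stringsAsFactors = FALSE)
}

# Apply the normality-gated transform to every screening variable once,
# so subgroup analyses share a single global transform decision.
prepare_screening <- function(observations, responses, predictors, ...) {
  cols <- unique(c(responses, predictors))
  out <- observations
  trans <- character(0)
  for (cc in cols) {
    nt <- normality_transform(observations[[cc]], ...)
    out[[cc]] <- nt$values
    trans[cc] <- nt$transform
  }
  attr(out, "transforms") <- trans
  out
}

#' Standardized coefficients within subgroups
#'
#' Computes one standardized regression coefficient per (response,
#' predictor, subgroup). Variables are transformed once globally (normality
#' screen) before grouping. Subgroups with fewer than `min_n` complete pairs
#' are emitted with `flag = "low_n"` and `NA` coefficient rather than
#' dropped.
#'
#' @param observations observation table (see [simulate_observations()]).
#' @param grouping `"continent"`, `"disturbance_type"`,
#'   `"impacted_vs_pristine"`, or `"global"`.
#' @param responses,predictors column names.
#' @param min_n minimum complete pairs for a reported coefficient.
#' @param mode `"bivariate"` (default; one simple standardized regression
#'   per predictor, the coefficient equals Pearson r) or `"adjusted"` (all
#'   predictors enter one multiple regression per response and subgroup;
#'   coefficients are mutually adjusted partial slopes).
#' @return tidy `data.frame` of coefficient records with a `flag` column.
#' @export
subgroup_coefficients <- function(observations,
                                  grouping = c("continent",
                                               "disturbance_type",
                                               "impacted_vs_pristine",
                                               "global"),
                                  responses = c("ch4_conc", "diff_flux"),
                                  predictors = c("TP", "NH4N", "TN", "NO3N"),
                                  min_n = 10,
                                  mode = c("bivariate", "adjusted")) {
  grouping <- match.arg(grouping)
  mode <- match.arg(mode)
  g <- switch(grouping,
    global = rep("global", nrow(observations)),
    continent = observations$continent_label,
    disturbance_type = disturbance_type(observations$landscape_class,
                                        observations$population_density),
    impacted_vs_pristine = ifelse(
      classify_human_impacted(observations$landscape_class,
                              observations$population_density),
      "impacted", "pristine"))
  prep <- prepare_screening(observations, responses, predictors)
  recs <- list()
  if (mode == "bivariate") {
    for (resp in responses) for (pred in predictors) for (lev in unique(g)) {
      i <- g == lev
      y <- prep[[resp]][i]; x <- prep[[pred]][i]
      nok <- sum(complete.cases(y, x))
      if (nok < max(min_n, 3) || sd(x, na.rm = TRUE) == 0 ||
          sd(y, na.rm = TRUE) == 0) {
        recs[[length(recs) + 1L]] <- data.frame(
          response = resp, predictor = pred, subgroup = lev,
          coefficient = NA_real_, n_used = nok, p_value = NA_real_,
          flag = "low_n", stringsAsFactors = FALSE)
      } else {
        r <- standardized_coefficient(y, x, resp, pred, lev)
        r$flag <- "ok"
        recs[[length(recs) + 1L]] <- r
      }
    }
  } else {
    for (resp in responses) for (lev in unique(g)) {
      i <- g == lev
      d <- prep[i, c(resp, predictors), drop = FALSE]
      d <- d[complete.cases(d), , drop = FALSE]
      nok <- nrow(d)
      degenerate <- nok < max(min_n, length(predictors) + 2) ||
        any(vapply(d, sd, numeric(1)) == 0)
      if (degenerate) {
        recs[[length(recs) + 1L]] <- data.frame(
          response = resp, predictor = predictors, subgroup = lev,
          coefficient = NA_real_, n_used = nok, p_value = NA_real_,
          flag = "low_n", stringsAsFactors = FALSE)
      } else {
        dz <- as.data.frame(lapply(d, zscore))
        fit <- lm(stats::reformulate(predictors, response = resp),
                  data = dz)
        sm <- suppressWarnings(summary(fit))$coefficients
        recs[[length(recs) + 1L]] <- data.frame(
          response = resp, predictor = predictors, subgroup = lev,
          coefficient = unname(coef(fit)[predictors]), n_used = nok,
          p_value = unname(sm[predictors, 4]), flag = "ok",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, recs)
}

# disturbance-type labels: urban / cropland / >20 people km-2 / others
disturbance_type <- function(landscape_class, population_density) {
  ifelse(landscape_class == "urban", "urban",
    ifelse(landscape_class == "cropland", "cropland",
      ifelse(population_density > 20, "dense", "others")))
}

#' Standardized coefficients along a population-density gradient
#'
#' For each density threshold, recomputes the standardized coefficient on
#' observations with density above the threshold, then smooths each
#' (response, predictor) coefficient sequence with loess.
#'
#' @param observations observation table.
#' @param thresholds strictly increasing density cutoffs (people km-2).
#' @param responses,predictors column names.
#' @param span loess span.
#' @param min_n minimum complete pairs per threshold.
#' @return `data.frame` with threshold, raw `coefficient`, `smoothed`
#'   coefficient, `n_used` and `flag`.
#' @export
density_gradient_curve <- function(observations, thresholds,
                                   responses = c("ch4_conc", "diff_flux"),
                                   predictors = c("TP", "NH4N"),
                                   span = 0.75, min_n = 10) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  prep <- prepare_screening(observations, responses, predictors)
  recs <- list()
  for (resp in responses) for (pred in predictors) {
    co <- rep(NA_real_, length(thresholds))
    nn <- integer(length(thresholds))
    for (k in seq_along(thresholds)) {
      i <- observations$population_density > thresholds[k]
      y <- prep[[resp]][i]; x <- prep[[pred]][i]
      nn[k] <- sum(complete.cases(y, x))
      if (nn[k] >= max(min_n, 3) && sd(x, na.rm = TRUE) > 0 &&
          sd(y, na.rm = TRUE) > 0)
        co[k] <- standardized_coefficient(y, x)$coefficient
    }
    sm <- rep(NA_real_, length(thresholds))
    ok <- !is.na(co)
    if (sum(ok) >= 4) {
      lo <- suppressWarnings(
        loess(co[ok] ~ thresholds[ok], span = span, degree = 1))
      sm[ok] <- predict(lo)
    } else sm[ok] <- co[ok]
    recs[[length(recs) + 1L]] <- data.frame(
      response = resp, predictor = pred, threshold = thresholds,
      coefficient = co, smoothed = sm, n_used = nn,
      flag = ifelse(ok, "ok", "low_n"), stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact rank-sum p-value when both samples have fewer than 50 values and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction (the switch point of [stats::wilcox.test()]).
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list with `statistic` (rank-sum W of `a`), `p_value`, `method`.
#' @export
wilcoxon_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  exact <- length(a) < 50 && length(b) < 50 &&
    !any(duplicated(c(a, b)))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}
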