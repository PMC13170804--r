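#' Ground-truth parameters for the synthetic river world
#'
#' Defines the generative response surface used by [simulate_observations()]
#' and [generate_network()]. The diffusive flux model is
#' \deqn{\ln F = a + \sum_s \beta_s \ln C_s + \beta_T T + \sum_j \gamma_j z_j
#'       + N(0, \sigma)}
#' where \eqn{C_s} are nutrient concentrations (TP, NH4-N, TN, NO3-N, mg/L),
#' \eqn{T} is water temperature (deg C) and \eqn{z_j} are standard-normal
#' latents behind the terrestrial predictors. CH4 concentration follows the
#' same form with its own intercept, noise, and betas scaled by
#' `conc_beta_scale`. Nutrients are drawn log-normally around class-specific
#' medians: `nutrient_base` times the landscape-class `enrichment_multipliers`.
#'
#' @param seed integer; the single source of randomness for all generators.
#' @param intercept intercept of ln diffusive flux (flux in mmol m-2 d-1).
#' @param beta_logTP,beta_logNH4,beta_logTN,beta_logNO3 elasticities on the
#'   natural-log nutrient concentrations (dimensionless).
#' @param beta_temp effect of water temperature on ln flux, per deg C.
#' @param terrestrial_betas named numeric; coefficients on the standard-normal
#'   latents behind terrestrial predictors (names must be a subset of
#'   [terrestrial_predictors()]).
#' @param noise_sd residual sd of ln flux (>= 0).
#' @param conc_intercept intercept of ln CH4 concentration (umol L-1).
#' @param conc_beta_scale multiplier applied to all flux betas to obtain the
#'   concentration betas.
#' @param conc_noise_sd residual sd of ln concentration.
#' @param nutrient_base named medians (mg/L) of TP, NH4N, TN, NO3N for a
#'   pristine river.
#' @param nutrient_sdlog log-scale sd of nutrient draws within a class.
#' @param enrichment_multipliers named positive factors (urban, cropland,
#'   dense, pristine) scaling all four nutrient medians.
#' @param class_probs landscape-class sampling probabilities.
#' @param ebullition_breaks strictly increasing population-density bin edges
#'   (people km-2), first 0, last Inf.
#' @param ebullition_ratios ebullitive-to-diffusive flux ratio per density
#'   bin (>= 0); length `length(ebullition_breaks) - 1`.
#' @param inactive_fraction expected fraction of reach-months that are dry or
#'   ice covered.
#'
#' @return an object of class `truth_params` (a validated named list).
#' @export
truth_params <- function(seed = 1L,
                         intercept = 1.0,
                         beta_logTP = 0.5,
                         beta_logNH4 = 0.4,
                         beta_logTN = 0.1,
                         beta_logNO3 = 0.05,
                         beta_temp = 0.04,
                         terrestrial_betas = c(gpp = 0.10,
                                               soil_respiration = 0.10,
                                               precipitation = 0.05,
                                               air_temp = 0.05),
                         noise_sd = 0.3,
                         conc_intercept = -1.0,
                         conc_beta_scale = 0.8,
                         conc_noise_sd = 0.3,
                         nutrient_base = c(TP = 0.02, NH4N = 0.01,
                                           TN = 0.5, NO3N = 0.3),
                         nutrient_sdlog = 0.8,
                         enrichment_multipliers = c(urban = 20, cropland = 10,
                                                    dense = 8, pristine = 1),
                         class_probs = c(urban = 0.2, cropland = 0.3,
                                         dense = 0.2, pristine = 0.3),
                         ebullition_breaks = c(0, 20, 200, Inf),
                         ebullition_ratios = c(low = 0.2, mid = 0.4,
                                               high = 0.6),
                         inactive_fraction = 0.1) {
  p <- list(seed = as.integer(seed), intercept = intercept,
            beta_logTP = beta_logTP, beta_logNH4 = beta_logNH4,
            beta_logTN = beta_logTN, beta_logNO3 = beta_logNO3,
            beta_temp = beta_temp, terrestrial_betas = terrestrial_betas,
            noise_sd = noise_sd, conc_intercept = conc_intercept,
            conc_beta_scale = conc_beta_scale, conc_noise_sd = conc_noise_sd,
            nutrient_base = nutrient_base, nutrient_sdlog = nutrient_sdlog,
            enrichment_multipliers = enrichment_multipliers,
            class_probs = class_probs,
            ebullition_breaks = ebullition_breaks,
            ebullition_ratios = ebullition_ratios,
            inactive_fraction = inactive_fraction)
  class(p) <- "truth_params"
  validate_truth_params(p)
}

validate_truth_params <- function(p) {
  stopifnot(inherits(p, "truth_params"))
  if (is.na(p$seed)) stop("seed must be an integer")
  if (p$noise_sd < 0 || p$conc_noise_sd < 0)
    stop("noise_sd must be >= 0")
  if (any(p$enrichment_multipliers <= 0))
    stop("enrichment multipliers must be > 0")
  if (any(p$ebullition_ratios < 0))
    stop("ebullition ratios must be >= 0")
  if (length(p$ebullition_ratios) != length(p$ebullition_breaks) - 1L)
    stop("need one ebullition ratio per density bin")
  if (is.unsorted(p$ebullition_breaks, strictly = TRUE))
    stop("ebullition_breaks must be strictly increasing")
  if (!setequal(names(p$nutrient_base), c("TP", "NH4N", "TN", "NO3N")))
    stop("nutrient_base must name TP, NH4N, TN, NO3N")
  known <- setdiff(names(p$class_probs),
                   c("urban", "cropland", "dense", "pristine"))
  if (length(known)) stop("unknown landscape class: ", known[1])
  if (p$inactive_fraction < 0 || p$inactive_fraction >= 1)
    stop("inactive_fraction must be in [0, 1)")
  extra <- setdiff(names(p$terrestrial_betas), terrestrial_predictors())
  if (length(extra)) stop("unknown terrestrial predictor: ", extra[1])
  p
}

#' Names of the terrestrial predictors in the modeling set
#'
#' Fourteen fixed names plus two configurable extras, giving the 16
#' terrestrial members of the 21-predictor vector (the five aquatic members
#' are TP, NH4N, TN, NO3N and water_temp).
#'
#' @param extra two additional predictor names declared by configuration.
#' @return character vector of length `14 + length(extra)`.
#' @export
terrestrial_predictors <- function(extra = c("ndvi", "wetland_fraction")) {
  c("slope", "elevation", "soil_sand", "soil_ph", "soc",
    "population_density", "artificial_land", "cropland_cover",
    "gpp", "npp", "soil_respiration", "groundwater_table",
    "air_temp", "precipitation", extra)
}

#' Names of the aquatic predictors
#' @return character vector of length 5.
#' @export
aquatic_predictors <- function() {
  c("TP", "NH4N", "TN", "NO3N", "water_temp")
}

#' Write / read truth parameters as YAML
#'
#' @param params a [truth_params()] object.
#' @param path file path.
#' @return `write_truth_params` returns `path` invisibly;
#'   `read_truth_params` returns a `truth_params` object.
#' @export
write_truth_params <- function(params, path) {
  validate_truth_params(params)
  yaml::write_yaml(params_to_yaml_list(params), path)
  invisible(path)
}

# named vectors must become maps (yaml drops names of atomic sequences);
# Inf does not round-trip through yaml scalars reliably, so tag it
params_to_yaml_list <- function(params) {
  x <- unclass(params)
  x$ebullition_breaks <- ifelse(is.infinite(x$ebullition_breaks),
                                ".inf", x$ebullition_breaks)
  for (f in c("terrestrial_betas", "nutrient_base", "enrichment_multipliers",
              "class_probs", "ebullition_ratios"))
    x[[f]] <- as.list(x[[f]])
  x
}

#' @rdname write_truth_params
#' @export
read_truth_params <- function(path) {
  x <- yaml::read_yaml(path)
  br <- suppressWarnings(as.numeric(unlist(x$ebullition_breaks)))
  br[is.na(br)] <- Inf
  x$ebullition_breaks <- br
  for (f in c("terrestrial_betas", "nutrient_base", "enrichment_multipliers",
              "class_probs", "ebullition_ratios"))
    x[[f]] <- unlist(x[[f]])
  do.call(truth_params, x)
}

#' Theoretical correlation between a log nutrient and the log response
#'
#' Pearson correlation implied by the truth parameters between
#' \eqn{\ln C_s} of one nutrient species and ln flux (or ln concentration),
#' accounting for the cross-species covariance induced by the shared
#' landscape-class enrichment multiplier.
#'
#' @param params a [truth_params()] object.
#' @param predictor one of `"TP"`, `"NH4N"`, `"TN"`, `"NO3N"`.
#' @param response `"ln_flux"` or `"ln_conc"`.
#' @return scalar correlation in [-1, 1].
#' @export
truth_theoretical_correlation <- function(params, predictor = "TP",
                                          response = c("ln_flux", "ln_conc")) {
  response <- match.arg(response)
  predictor <- match.arg(predictor, c("TP", "NH4N", "TN", "NO3N"))
  m <- truth_moments(params)
  b <- c(TP = params$beta_logTP, NH4N = params$beta_logNH4,
         TN = params$beta_logTN, NO3N = params$beta_logNO3)
  bt <- params$beta_temp
  gb <- params$terrestrial_betas
  sig <- params$noise_sd
  if (response == "ln_conc") {
    b <- b * params$conc_beta_scale
    bt <- bt * params$conc_beta_scale
    gb <- gb * params$conc_beta_scale
    sig <- params$conc_noise_sd
  }
  v_sig <- sum(b^2) * m$var_ln_nutrient +
    m$cov_ln_nutrients * (sum(b)^2 - sum(b^2)) +
    bt^2 * m$var_temp + sum(gb^2)
  cv <- b[predictor] * m$var_ln_nutrient +
    sum(b[setdiff(names(b), predictor)]) * m$cov_ln_nutrients
  unname(cv / sqrt(m$var_ln_nutrient * (v_sig + sig^2)))
}

# Analytic moments of the generator, used for theoretical-R2 oracles.
# ln C_s = ln base_s + ln mult(class) + N(0, sdlog^2); the class log
# multiplier is shared across species, inducing cross-species covariance.
truth_moments <- function(params) {
  pr <- params$class_probs / sum(params$class_probs)
  lm_ <- log(params$enrichment_multipliers[names(pr)])
  mu_m <- sum(pr * lm_)
  var_m <- sum(pr * (lm_ - mu_m)^2)
  var_ln <- params$nutrient_sdlog^2 + var_m
  # water temperature: seasonal sine (amplitude 8, uniform months) + N(0,3^2)
  months <- 1:12
  seas <- 8 * sin(2 * pi * (months - 4) / 12)
  var_t <- mean((seas - mean(seas))^2) + 9
  list(var_ln_nutrient = var_ln, cov_ln_nutrients = var_m, var_temp = var_t)
}

#' Theoretical R-squared of the generative model
#'
#' Computes var(signal) / (var(signal) + noise^2) analytically from the
#' truth parameters, accounting for the cross-species covariance induced by
#' the shared landscape-class enrichment multiplier.
#'
#' @param params a [truth_params()] object.
#' @param response `"ln_flux"` or `"ln_conc"`.
#' @return scalar theoretical R-squared in [0, 1].
#' @export
truth_theoretical_r2 <- function(params, response = c("ln_flux", "ln_conc")) {
  response <- match.arg(response)
  m <- truth_moments(params)
  b <- c(params$beta_logTP, params$beta_logNH4, params$beta_logTN,
         params$beta_logNO3)
  bt <- params$beta_temp
  gb <- params$terrestrial_betas
  sig <- params$noise_sd
  if (response == "ln_conc") {
    b <- b * params$conc_beta_scale
    bt <- bt * params$conc_beta_scale
    gb <- gb * params$conc_beta_scale
    sig <- params$conc_noise_sd
  }
  v_sig <- sum(b^2) * m$var_ln_nutrient +
    m$cov_ln_nutrients * (sum(b)^2 - sum(b^2)) +
    bt^2 * m$var_temp + sum(gb^2)
  v_sig / (v_sig + sig^2)
}
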