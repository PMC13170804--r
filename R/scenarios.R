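# Counterfactual nutrient-reduction scenarios: edit the four nutrient
# concentration fields of a predictor table, re-predict, and account
# mitigation as current minus scenario emissions.

NUTRIENT_FIELDS <- c("TP", "NH4N", "TN", "NO3N")

#' Specify a nutrient-reduction scenario
#'
#' Three kinds: `"half"` (all four nutrient concentrations halved),
#' `"sustainable"` (country-specific reduction ratio applied to the
#' nitrogen species and, as a co-limiting assumption, the same ratio to
#' phosphorus), `"pristine"` (concentrations replaced by per-basin pristine
#' levels; a regional-median fallback handles basins without pristine
#' rivers).
#'
#' @param kind `"sustainable"`, `"half"` or `"pristine"`.
#' @param country_reduction_ratio named numeric, country id to reduction
#'   fraction in [0, 1] (sustainable only).
#' @param pristine_lookup `data.frame` with `basin_id` and columns TP,
#'   NH4N, TN, NO3N in mg/L (pristine only).
#' @param fallback optional named numeric of region-median pristine
#'   concentrations used when a basin is missing from the lookup.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("half", "sustainable", "pristine"),
                          country_reduction_ratio = NULL,
                          pristine_lookup = NULL, fallback = NULL) {
  kind <- match.arg(kind)
  if (kind == "sustainable") {
    if (is.null(country_reduction_ratio) ||
        is.null(names(country_reduction_ratio)))
      stop("sustainable scenario needs a named country_reduction_ratio")
    if (any(country_reduction_ratio < 0 | country_reduction_ratio > 1))
      stop("reduction ratios must be in [0, 1]")
  }
  if (kind == "pristine") {
    if (is.null(pristine_lookup))
      stop("pristine scenario needs a pristine_lookup table")
    need <- c("basin_id", NUTRIENT_FIELDS)
    missing <- setdiff(need, names(pristine_lookup))
    if (length(missing))
      stop("pristine_lookup missing columns: ",
           paste(missing, collapse = ", "))
    if (any(as.matrix(pristine_lookup[NUTRIENT_FIELDS]) < 0, na.rm = TRUE))
      stop("pristine concentrations must be >= 0")
  }
  structure(list(kind = kind,
                 country_reduction_ratio = country_reduction_ratio,
                 pristine_lookup = pristine_lookup, fallback = fallback),
            class = "scenario_spec")
}

#' Derive a per-basin pristine nutrient lookup from observations
#'
#' Median nutrient concentrations of non-human-impacted sites per basin
#' label, with the overall pristine medians as the fallback.
#'
#' @param observations observation table with a basin column.
#' @param basin_col column holding the basin label.
#' @return a `pristine` [scenario_spec()].
#' @export
pristine_spec_from_observations <- function(observations,
                                            basin_col = "continent_label") {
  pri <- observations[!classify_human_impacted(
    observations$landscape_class, observations$population_density), ,
    drop = FALSE]
  if (!nrow(pri)) stop("no pristine observations to derive the lookup from")
  med <- do.call(rbind, lapply(split(pri, pri[[basin_col]]), function(d)
    data.frame(basin_id = d[[basin_col]][1],
               TP = median(d$TP, na.rm = TRUE),
               NH4N = median(d$NH4N, na.rm = TRUE),
               TN = median(d$TN, na.rm = TRUE),
               NO3N = median(d$NO3N, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(med) <- NULL
  fallback <- c(TP = median(pri$TP, na.rm = TRUE),
                NH4N = median(pri$NH4N, na.rm = TRUE),
                TN = median(pri$TN, na.rm = TRUE),
                NO3N = median(pri$NO3N, na.rm = TRUE))
  scenario_spec("pristine", pristine_lookup = med, fallback = fallback)
}

#' Apply a nutrient-reduction scenario to a predictor table
#'
#' Only the four nutrient fields (TP, NH4N, TN, NO3N) change; every other
#' column is untouched. The returned table is tagged with the scenario
#' kind; re-applying the same scenario is a no-op (idempotent).
#'
#' @param cells a table with the four nutrient columns; the sustainable
#'   kind needs `country_id`, the pristine kind `basin_id`.
#' @param spec a [scenario_spec()].
#' @return the edited table, with attribute `scenario`.
#' @export
apply_scenario <- function(cells, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (identical(attr(cells, "scenario"), spec$kind)) {
    message("scenario '", spec$kind, "' already applied; returning as-is")
    return(cells)
  }
  missing <- setdiff(NUTRIENT_FIELDS, names(cells))
  if (length(missing))
    stop("table missing nutrient fields: ", paste(missing, collapse = ", "))
  out <- cells
  if (spec$kind == "half") {
    for (f in NUTRIENT_FIELDS) out[[f]] <- out[[f]] * 0.5
  } else if (spec$kind == "sustainable") {
    if (!"country_id" %in% names(cells))
      stop("sustainable scenario needs a country_id column")
    ratio <- spec$country_reduction_ratio[cells$country_id]
    if (anyNA(ratio))
      stop("no reduction ratio for country ",
           cells$country_id[is.na(ratio)][1])
    for (f in NUTRIENT_FIELDS) out[[f]] <- out[[f]] * (1 - unname(ratio))
  } else { # pristine
    if (!"basin_id" %in% names(cells))
      stop("pristine scenario needs a basin_id column")
    idx <- match(cells$basin_id, spec$pristine_lookup$basin_id)
    for (f in NUTRIENT_FIELDS) {
      v <- spec$pristine_lookup[[f]][idx]
      if (anyNA(v)) {
        if (is.null(spec$fallback))
          stop("basin ", cells$basin_id[is.na(v)][1],
               " missing from pristine lookup and no fallback given")
        v[is.na(v)] <- spec$fallback[[f]]
      }
      out[[f]] <- v
    }
    out$pristine_fallback <- is.na(idx)
  }
  attr(out, "scenario") <- spec$kind
  out
}

#' Mitigation accounting between two emission aggregates
#'
#' reduction = current - scenario, absolute (Tg CH4 yr-1) and as a
#' percentage of current, per cell and per region.
#'
#' @param current,scenario outputs of [annual_aggregate()] on identical
#'   cell sets and masking.
#' @return list: `cell` (per-cell reductions), `regional`, and `total`
#'   (absolute Tg and percent).
#' @export
mitigation <- function(current, scenario) {
  cur <- current$cell_annual
  scn <- scenario$cell_annual
  if (!setequal(cur$cell_id, scn$cell_id))
    stop("mismatched cell sets between current and scenario tables")
  scn <- scn[match(cur$cell_id, scn$cell_id), , drop = FALSE]
  cell <- data.frame(cell_id = cur$cell_id,
                     current_g = cur$total_g, scenario_g = scn$total_g,
                     reduction_g = cur$total_g - scn$total_g,
                     stringsAsFactors = FALSE)
  cell$reduction_pct <- ifelse(cell$current_g > 0,
                               100 * cell$reduction_g / cell$current_g, 0)
  key <- paste(current$regional$region_type, current$regional$region)
  skey <- paste(scenario$regional$region_type, scenario$regional$region)
  sreg <- scenario$regional[match(key, skey), , drop = FALSE]
  regional <- data.frame(region_type = current$regional$region_type,
                         region = current$regional$region,
                         current_Tg = current$regional$total_Tg,
                         scenario_Tg = sreg$total_Tg,
                         reduction_Tg = current$regional$total_Tg -
                           sreg$total_Tg,
                         stringsAsFactors = FALSE)
  regional$reduction_pct <- ifelse(regional$current_Tg > 0,
                                   100 * regional$reduction_Tg /
                                     regional$current_Tg, 0)
  list(cell = cell, regional = regional,
       total = c(reduction_Tg = current$total_Tg - scenario$total_Tg,
                 reduction_pct = if (current$total_Tg > 0)
                   100 * (current$total_Tg - scenario$total_Tg) /
                     current$total_Tg else 0))
}
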