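# Upscaling: nutrient concentrations from loads and runoff, monthly river
# surface area with Strahler-order extrapolation and dry/ice masking,
# flux-to-mass conversion (molar mass 16.04 g/mol CH4), ebullition
# addition, and annual/regional aggregation.

CH4_MOLAR_MASS <- 16.04 # g per mol = mg per mmol

# non-leap calendar; config switch adds the leap day to February
month_days <- function(leap = FALSE) {
  d <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  if (leap) d[2] <- 29
  d
}

#' Grid-cell nutrient concentration from load and runoff
#'
#' concentration (mg/L) = 1000 * load (kg/month) / runoff (m3/month).
#'
#' @param load nutrient load, kg per month (>= 0).
#' @param runoff cumulative runoff, m3 per month (> 0).
#' @param cell_id optional label(s) used in error messages.
#' @return concentration in mg/L, vectorized.
#' @export
cell_nutrient_concentration <- function(load, runoff, cell_id = NULL) {
  bad <- !is.finite(runoff) | runoff <= 0
  if (any(bad)) {
    lab <- if (is.null(cell_id)) which(bad)[1] else cell_id[bad][1]
    stop("non-positive runoff in cell ", lab)
  }
  if (any(load < 0)) stop("negative nutrient load")
  1000 * load / runoff
}

#' Monthly river surface area of a grid cell
#'
#' Sum over the cell's active reaches of monthly width times length;
#' reaches flagged inactive (dry or ice-covered) contribute zero.
#'
#' @param reaches reach table rows of one cell.
#' @param month calendar month 1-12.
#' @return area in m2.
#' @export
monthly_surface_area <- function(reaches, month) {
  stopifnot(month %in% 1:12)
  w <- reaches[[sprintf("width_m%02d", month)]]
  a <- as.logical(reaches[[sprintf("active_m%02d", month)]])
  if (any(w < 0)) stop("negative reach width")
  sum(w * reaches$length * as.numeric(a))
}

#' Extrapolate river surface area to unmapped Strahler orders
#'
#' Fits ln(area) linearly on stream order over the observed orders and
#' evaluates the fit at each target order (small streams missing from the
#' reach network).
#'
#' @param area_by_order named numeric; names are observed Strahler orders,
#'   values their total areas (m2, > 0).
#' @param target_orders integer orders to extrapolate to.
#' @return named numeric of extrapolated areas (m2).
#' @export
strahler_extrapolate <- function(area_by_order, target_orders) {
  area_by_order <- area_by_order[area_by_order > 0]
  if (length(area_by_order) < 2)
    stop("need at least 2 observed Strahler orders for extrapolation")
  ord <- as.numeric(names(area_by_order))
  fit <- lm(log(area_by_order) ~ ord)
  pred <- exp(unname(coef(fit)[1] + coef(fit)[2] * target_orders))
  setNames(pred, target_orders)
}

#' Monthly CH4 mass emitted by one cell
#'
#' flux (mmol m-2 d-1) x area (m2) x days x 16.04 mg/mmol, in grams.
#'
#' @param flux CH4 flux, mmol m-2 d-1 (>= 0).
#' @param area river surface area, m2 (>= 0).
#' @param days days in the month (28-31).
#' @return grams of CH4, vectorized.
#' @export
cell_monthly_emission <- function(flux, area, days) {
  if (any(!days %in% 28:31)) stop("invalid day count: ", days[!days %in% 28:31][1])
  if (any(flux < 0)) stop("negative flux")
  if (any(area < 0)) stop("negative area")
  flux * area * days * CH4_MOLAR_MASS / 1000
}

#' Add ebullitive emissions from population-density groups
#'
#' total = diffusive x (1 + ratio(group)); per-component accounting kept.
#'
#' @param diffusive diffusive emissions (any mass unit), vectorized.
#' @param population_density people km-2, recycled against `diffusive`.
#' @param breaks,ratios density-group definition (see [ebullition_ratio()]).
#' @return `data.frame` with `diffusive`, `ebullitive`, `total`.
#' @export
add_ebullition <- function(diffusive, population_density, breaks, ratios) {
  r <- ebullition_ratio(population_density, breaks, ratios)
  data.frame(diffusive = diffusive, ebullitive = diffusive * r,
             total = diffusive * (1 + r))
}

#' Build the per-cell-month emission table
#'
#' Combines predicted fluxes with monthly masked areas and the ebullition
#' partition into an emission table: grams of CH4 per (cell, month,
#' component).
#'
#' @param fluxes `data.frame` with `cell_id`, `month`, `flux` (mmol m-2
#'   d-1); optionally member columns `flux_rf`, `flux_gbt`, `flux_svr` for
#'   spread-based uncertainty.
#' @param areas `data.frame` with `cell_id`, `month`, `area_m2` (masked,
#'   extrapolation included).
#' @param cells grid-cell table (for population density).
#' @param breaks,ratios ebullition density-group definition.
#' @param leap use a leap-year calendar.
#' @return `data.frame`: cell_id, month, area_m2, flux, diffusive_g,
#'   ebullitive_g, total_g (and member totals when members supplied).
#' @export
emission_table <- function(fluxes, areas, cells, breaks, ratios,
                           leap = FALSE) {
  x <- merge(fluxes, areas, by = c("cell_id", "month"))
  if (nrow(x) != nrow(fluxes))
    stop("fluxes and areas tables do not align on (cell_id, month)")
  x <- merge(x, cells[, c("cell_id", "population_density")], by = "cell_id")
  days <- month_days(leap)[x$month]
  dif <- cell_monthly_emission(x$flux, x$area_m2, days)
  eb <- add_ebullition(dif, x$population_density, breaks, ratios)
  out <- data.frame(cell_id = x$cell_id, month = x$month,
                    area_m2 = x$area_m2, flux = x$flux,
                    diffusive_g = eb$diffusive, ebullitive_g = eb$ebullitive,
                    total_g = eb$total, stringsAsFactors = FALSE)
  for (m in c("flux_rf", "flux_gbt", "flux_svr")) {
    if (m %in% names(x)) {
      dm <- cell_monthly_emission(x[[m]], x$area_m2, days)
      ebm <- add_ebullition(dm, x$population_density, breaks, ratios)
      out[[sub("flux", "total_g", m)]] <- ebm$total
    }
  }
  out[order(out$cell_id, out$month), , drop = FALSE]
}

#' Monthly masked river surface areas per cell
#'
#' Computes per-(cell, month) surface area from the reach table (active
#' reaches only) and, when a cell's reaches span at least two Strahler
#' orders, adds log-linear extrapolated area for the unmapped smaller
#' orders (`target_orders` below the cell's minimum observed order).
#'
#' @param reaches reach table; `cells` grid-cell table.
#' @param extrapolate_orders extrapolate area for unmapped orders below the
#'   observed minimum, down to order 1.
#' @return `data.frame`: cell_id, month, area_m2.
#' @export
cell_monthly_areas <- function(reaches, cells, extrapolate_orders = TRUE) {
  out <- expand.grid(cell_id = cells$cell_id, month = 1:12,
                     stringsAsFactors = FALSE)
  out$area_m2 <- 0
  for (ci in cells$cell_id) {
    rs <- reaches[reaches$grid_cell_id == ci, , drop = FALSE]
    if (!nrow(rs)) next
    for (m in 1:12) {
      w <- rs[[sprintf("width_m%02d", m)]]
      act <- as.logical(rs[[sprintf("active_m%02d", m)]])
      contrib <- w * rs$length * as.numeric(act)
      area <- sum(contrib)
      if (extrapolate_orders) {
        by_ord <- tapply(contrib, rs$strahler_order, sum)
        by_ord <- by_ord[by_ord > 0]
        if (length(by_ord) >= 2) {
          min_ord <- min(as.numeric(names(by_ord)))
          if (min_ord > 1)
            area <- area + sum(strahler_extrapolate(by_ord,
                                                    seq_len(min_ord - 1)))
        }
      }
      out$area_m2[out$cell_id == ci & out$month == m] <- area
    }
  }
  out
}

#' Annual and regional emission aggregates
#'
#' Sums the per-cell-month table to per-cell annual emissions and to
#' regional annual totals (climate zone, continent, income group) in
#' Tg CH4 yr-1. When member totals are present, regional uncertainty is
#' half the member range.
#'
#' @param emissions output of [emission_table()] (12 months per cell;
#'   masked months as zero area/emission).
#' @param cells grid-cell table with region labels.
#' @return list: `cell_annual` (g and Tg), `regional` (Tg by region type),
#'   `total_Tg`.
#' @export
annual_aggregate <- function(emissions, cells) {
  cnt <- table(emissions$cell_id)
  if (any(cnt != 12))
    stop("every cell needs 12 monthly rows (got ",
         paste(names(cnt)[cnt != 12][1]), ")")
  lab <- cells[, c("cell_id", "climate_zone", "continent", "income_group")]
  if (anyNA(lab)) stop("cell missing region label")
  if (!all(emissions$cell_id %in% lab$cell_id))
    stop("emission table contains cells absent from the cell table")
  agg <- function(v) tapply(v, emissions$cell_id, sum)
  cell_annual <- data.frame(cell_id = names(agg(emissions$total_g)),
                            diffusive_g = as.numeric(agg(emissions$diffusive_g)),
                            ebullitive_g = as.numeric(agg(emissions$ebullitive_g)),
                            total_g = as.numeric(agg(emissions$total_g)),
                            stringsAsFactors = FALSE)
  cell_annual$total_Tg <- cell_annual$total_g / 1e12
  cell_annual <- merge(cell_annual, lab, by = "cell_id")
  member_cols <- intersect(c("total_g_rf", "total_g_gbt", "total_g_svr"),
                           names(emissions))
  for (m in member_cols)
    cell_annual[[m]] <- as.numeric(agg(emissions[[m]]))[
      match(cell_annual$cell_id, names(agg(emissions$total_g)))]
  regional <- do.call(rbind, lapply(
    c("climate_zone", "continent", "income_group"), function(rt) {
      tot <- tapply(cell_annual$total_g, cell_annual[[rt]], sum) / 1e12
      out <- data.frame(region_type = rt, region = names(tot),
                        total_Tg = as.numeric(tot), stringsAsFactors = FALSE)
      if (length(member_cols) >= 2) {
        mem <- sapply(member_cols, function(m)
          as.numeric(tapply(cell_annual[[m]], cell_annual[[rt]], sum)) / 1e12)
        mem <- matrix(mem, nrow = nrow(out))
        out$uncertainty_Tg <- (apply(mem, 1, max) - apply(mem, 1, min)) / 2
      } else out$uncertainty_Tg <- NA_real_
      out
    }))
  rownames(regional) <- NULL
  list(cell_annual = cell_annual, regional = regional,
       total_Tg = sum(cell_annual$total_g) / 1e12)
}
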