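test_that("load/runoff concentration arithmetic is exact", {
  expect_identical(cell_nutrient_concentration(100, 1e6), 0.1)
  expect_identical(cell_nutrient_concentration(0, 1e6), 0)
  expect_equal(cell_nutrient_concentration(2 * 100, 2 * 1e6),
               cell_nutrient_concentration(100, 1e6))
  expect_error(cell_nutrient_concentration(10, 0, cell_id = "G1"), "G1")
  expect_error(cell_nutrient_concentration(-1, 10), "negative")
})

test_that("monthly surface area sums active reach areas", {
  r <- data.frame(length = c(1000, 2000), strahler_order = c(2, 3))
  for (m in 1:12) {
    r[[sprintf("width_m%02d", m)]] <- c(10, 5)
    r[[sprintf("active_m%02d", m)]] <- TRUE
  }
  expect_equal(monthly_surface_area(r[1, ], 1), 1e4)
  expect_equal(monthly_surface_area(r, 1), 1e4 + 1e4)
  r$active_m01 <- FALSE
  expect_equal(monthly_surface_area(r, 1), 0)
  r$width_m02[1] <- -1
  expect_error(monthly_surface_area(r, 2), "negative")
})

test_that("Strahler extrapolation matches the log-linear closed form", {
  expect_equal(strahler_extrapolate(c(`3` = 400, `2` = 200), 1)[["1"]], 100,
               tolerance = 1e-9)
  expect_equal(strahler_extrapolate(c(`2` = 7, `4` = 7, `6` = 7), c(1, 3)),
               c(`1` = 7, `3` = 7), tolerance = 1e-9)
  perfect <- c(`2` = 50, `3` = 100, `4` = 200) # doubling per order
  expect_equal(strahler_extrapolate(perfect, 1)[["1"]], 25,
               tolerance = 1e-9)
  fit_resid <- residuals(lm(log(perfect) ~ as.numeric(names(perfect))))
  expect_lt(max(abs(fit_resid)), 1e-12)
  expect_error(strahler_extrapolate(c(`3` = 400), 1), "at least 2")
})

test_that("flux-to-mass conversion uses 16.04 g/mol", {
  expect_equal(cell_monthly_emission(1, 1, 30), 0.4812, tolerance = 1e-12)
  expect_equal(cell_monthly_emission(1, 0, 30), 0)
  expect_equal(cell_monthly_emission(2.5, 1e6, 30), 2.5e6 * 30 * 16.04 / 1000,
               tolerance = 1e-12)
  expect_error(cell_monthly_emission(1, 1, 27), "day count")
  # unit round trip: g back to mmol recovers the input exactly
  g <- cell_monthly_emission(3.7, 123, 31)
  expect_equal(g * 1000 / 16.04 / 31 / 123, 3.7, tolerance = 1e-12)
})

test_that("ebullition addition uses the group-specific ratio", {
  br <- c(0, 20, Inf); ra <- c(0.0, 1.0)
  out <- add_ebullition(c(10, 10), c(5, 100), br, ra)
  expect_equal(out$total, c(10, 20))
  expect_equal(out$ebullitive, c(0, 10))
  expect_equal(add_ebullition(7, 5, c(0, Inf), 0)$total, 7)
})

test_that("annual aggregation conserves mass across partitions", {
  w <- tiny_world(seed = 51, n_cells = 6, reaches_per_cell = 4)
  areas <- cell_monthly_areas(w$reaches, w$cells)
  set.seed(51)
  fluxes <- expand.grid(cell_id = w$cells$cell_id, month = 1:12,
                        stringsAsFactors = FALSE)
  fluxes$flux <- runif(nrow(fluxes), 0.5, 8)
  em <- emission_table(fluxes, areas, w$cells,
                       w$params$ebullition_breaks,
                       w$params$ebullition_ratios)
  agg <- annual_aggregate(em, w$cells)
  # annual = sum of months, per cell
  expect_equal(agg$cell_annual$total_g[order(agg$cell_annual$cell_id)],
               as.numeric(tapply(em$total_g, em$cell_id, sum)),
               tolerance = 1e-12)
  # every regional partition reproduces the grand total
  for (rt in c("climate_zone", "continent", "income_group")) {
    part <- agg$regional[agg$regional$region_type == rt, ]
    expect_equal(sum(part$total_Tg), agg$total_Tg, tolerance = 1e-9)
  }
  expect_equal(agg$total_Tg, sum(em$total_g) / 1e12, tolerance = 1e-12)
  # diffusive + ebullitive = total
  expect_equal(em$diffusive_g + em$ebullitive_g, em$total_g,
               tolerance = 1e-12)
})

test_that("masking a reach-month never increases any emission", {
  w <- tiny_world(seed = 52, n_cells = 3, reaches_per_cell = 3)
  reaches2 <- w$reaches
  reaches2$active_m06 <- FALSE
  a1 <- cell_monthly_areas(w$reaches, w$cells)
  a2 <- cell_monthly_areas(reaches2, w$cells)
  expect_true(all(a2$area_m2 <= a1$area_m2 + 1e-12))
  fluxes <- expand.grid(cell_id = w$cells$cell_id, month = 1:12,
                        stringsAsFactors = FALSE)
  fluxes$flux <- 2
  mk <- function(a) annual_aggregate(
    emission_table(fluxes, a, w$cells, w$params$ebullition_breaks,
                   w$params$ebullition_ratios), w$cells)
  g1 <- mk(a1); g2 <- mk(a2)
  expect_true(all(g2$cell_annual$total_g <= g1$cell_annual$total_g + 1e-9))
  expect_lte(g2$total_Tg, g1$total_Tg)
})

test_that("increasing a cell's flux weakly increases its annual emission", {
  w <- tiny_world(seed = 53, n_cells = 3, reaches_per_cell = 2)
  areas <- cell_monthly_areas(w$reaches, w$cells)
  fluxes <- expand.grid(cell_id = w$cells$cell_id, month = 1:12,
                        stringsAsFactors = FALSE)
  fluxes$flux <- 1
  f2 <- fluxes
  f2$flux[f2$cell_id == w$cells$cell_id[1]] <- 3
  mk <- function(f) annual_aggregate(
    emission_table(f, areas, w$cells, w$params$ebullition_breaks,
                   w$params$ebullition_ratios), w$cells)
  g1 <- mk(fluxes); g2 <- mk(f2)
  expect_true(all(g2$cell_annual$total_g >= g1$cell_annual$total_g - 1e-9))
  expect_gte(g2$total_Tg, g1$total_Tg)
})

test_that("aggregation guards incomplete cells and missing labels", {
  w <- tiny_world(seed = 54, n_cells = 2, reaches_per_cell = 2)
  areas <- cell_monthly_areas(w$reaches, w$cells)
  fluxes <- expand.grid(cell_id = w$cells$cell_id, month = 1:12,
                        stringsAsFactors = FALSE)
  fluxes$flux <- 1
  em <- emission_table(fluxes, areas, w$cells,
                       w$params$ebullition_breaks,
                       w$params$ebullition_ratios)
  expect_error(annual_aggregate(em[-1, ], w$cells), "12 monthly rows")
  cells_bad <- w$cells
  cells_bad$continent[1] <- NA
  expect_error(annual_aggregate(em, cells_bad), "region label")
})
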