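make_predictor_table <- function(n = 6) {
  data.frame(cell_id = sprintf("G%02d", 1:n),
             TP = seq(0.2, 0.7, length.out = n),
             NH4N = seq(0.1, 0.35, length.out = n),
             TN = seq(1, 2, length.out = n),
             NO3N = seq(0.5, 1, length.out = n),
             water_temp = 15, slope = 3,
             country_id = rep(c("C1", "C2"), length.out = n),
             basin_id = rep(c("B1", "B2", "B3"), length.out = n),
             stringsAsFactors = FALSE)
}

test_that("half scenario halves exactly the four nutrient fields", {
  tab <- make_predictor_table()
  out <- apply_scenario(tab, scenario_spec("half"))
  expect_equal(out$TP, tab$TP * 0.5)
  expect_equal(out$NH4N, tab$NH4N * 0.5)
  expect_equal(out$TN, tab$TN * 0.5)
  expect_equal(out$NO3N, tab$NO3N * 0.5)
  other <- setdiff(names(tab), c("TP", "NH4N", "TN", "NO3N"))
  expect_identical(out[other], tab[other])
  expect_equal(out$TP[1], 0.1) # 0.2 -> 0.1
})

test_that("sustainable scenario applies country ratios to all species", {
  tab <- make_predictor_table()
  spec <- scenario_spec("sustainable",
                        country_reduction_ratio = c(C1 = 0.3, C2 = 0.1))
  out <- apply_scenario(tab, spec)
  expect_equal(out$NO3N[1], tab$NO3N[1] * 0.7)
  expect_equal(out$TP[1], tab$TP[1] * 0.7)   # equivalent P reduction
  expect_equal(out$TP[2], tab$TP[2] * 0.9)
  expect_error(apply_scenario(within(tab, country_id[1] <- "C9"), spec),
               "C9")
  expect_error(scenario_spec("sustainable",
                             country_reduction_ratio = c(C1 = 1.5)),
               "0, 1")
})

test_that("pristine scenario replaces concentrations from the lookup", {
  tab <- make_predictor_table()
  lk <- data.frame(basin_id = c("B1", "B2"), TP = 0.01, NH4N = 0.005,
                   TN = 0.3, NO3N = 0.2, stringsAsFactors = FALSE)
  fb <- c(TP = 0.02, NH4N = 0.01, TN = 0.4, NO3N = 0.25)
  out <- apply_scenario(tab, scenario_spec("pristine", pristine_lookup = lk,
                                           fallback = fb))
  expect_equal(out$TP[tab$basin_id == "B1"],
               rep(0.01, sum(tab$basin_id == "B1")))
  expect_equal(out$TP[tab$basin_id == "B3"],
               rep(0.02, sum(tab$basin_id == "B3")))
  expect_true(all(out$pristine_fallback[tab$basin_id == "B3"]))
  expect_error(apply_scenario(tab, scenario_spec("pristine",
                                                 pristine_lookup = lk)),
               "fallback")
})

test_that("scenario application is idempotent and metadata-tagged", {
  tab <- make_predictor_table()
  out <- apply_scenario(tab, scenario_spec("half"))
  expect_equal(attr(out, "scenario"), "half")
  expect_message(out2 <- apply_scenario(out, scenario_spec("half")),
                 "already applied")
  expect_equal(out2$TP, out$TP)
})

test_that("pristine lookup derives from non-impacted observations", {
  obs <- simulate_observations(800, truth_params(seed = 61))
  spec <- pristine_spec_from_observations(obs)
  pri <- obs[!classify_human_impacted(obs$landscape_class,
                                      obs$population_density), ]
  for (b in spec$pristine_lookup$basin_id) {
    expect_equal(spec$pristine_lookup$TP[spec$pristine_lookup$basin_id == b],
                 median(pri$TP[pri$continent_label == b]))
  }
  expect_equal(spec$fallback[["TP"]], median(pri$TP))
})

test_that("mitigation of an identical scenario is exactly zero", {
  w <- tiny_world(seed = 62, n_cells = 4, reaches_per_cell = 2)
  areas <- cell_monthly_areas(w$reaches, w$cells)
  fluxes <- expand.grid(cell_id = w$cells$cell_id, month = 1:12,
                        stringsAsFactors = FALSE)
  fluxes$flux <- 2.5
  agg <- annual_aggregate(emission_table(fluxes, areas, w$cells,
                                         w$params$ebullition_breaks,
                                         w$params$ebullition_ratios),
                          w$cells)
  mit <- mitigation(agg, agg)
  expect_true(all(mit$cell$reduction_g == 0))
  expect_true(all(mit$regional$reduction_Tg == 0))
  expect_identical(unname(mit$total["reduction_Tg"]), 0)
})

test_that("mitigation arithmetic and scale invariance hold", {
  w <- tiny_world(seed = 63, n_cells = 3, reaches_per_cell = 2)
  areas <- cell_monthly_areas(w$reaches, w$cells)
  fx <- expand.grid(cell_id = w$cells$cell_id, month = 1:12,
                    stringsAsFactors = FALSE)
  f_cur <- within(fx, flux <- 10)
  f_scn <- within(fx, flux <- 6)
  mk <- function(f) annual_aggregate(
    emission_table(f, areas, w$cells, w$params$ebullition_breaks,
                   w$params$ebullition_ratios), w$cells)
  mit <- mitigation(mk(f_cur), mk(f_scn))
  expect_equal(unname(mit$total["reduction_pct"]), 40, tolerance = 1e-9)
  expect_equal(mit$cell$reduction_g, mit$cell$current_g * 0.4,
               tolerance = 1e-9)
  # scaling both tables by a global unit change leaves percentages alone
  f_cur2 <- within(fx, flux <- 10 * 3)
  f_scn2 <- within(fx, flux <- 6 * 3)
  mit2 <- mitigation(mk(f_cur2), mk(f_scn2))
  expect_equal(mit2$regional$reduction_pct, mit$regional$reduction_pct,
               tolerance = 1e-9)
  bad <- mk(f_scn)
  bad$cell_annual <- bad$cell_annual[-1, ]
  expect_error(mitigation(mk(f_cur), bad), "mismatched cell sets")
})

test_that("pristine beats half when pristine levels are below half", {
  tab <- make_predictor_table()
  lk <- data.frame(basin_id = c("B1", "B2", "B3"), TP = 0.001,
                   NH4N = 0.001, TN = 0.01, NO3N = 0.01,
                   stringsAsFactors = FALSE)
  half <- apply_scenario(tab, scenario_spec("half"))
  pris <- apply_scenario(tab, scenario_spec("pristine",
                                            pristine_lookup = lk))
  for (f in c("TP", "NH4N", "TN", "NO3N"))
    expect_true(all(pris[[f]] <= half[[f]]))
})
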