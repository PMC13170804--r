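# Delimited-table writers/readers for the three pipeline inputs.
# Columns and units are documented in the schema accessors; readers
# validate presence and basic invariants so failures happen at load time.

obs_required_cols <- function() {
  c("site_id", "continent_label", "landscape_class", "population_density",
    "month", "TP", "NH4N", "TN", "NO3N", "DOC", "DO", "water_temp", "pH",
    "chl_a", "ch4_conc", "diff_flux")
}

reach_required_cols <- function() {
  c("reach_id", "grid_cell_id", "length", "strahler_order",
    "population_density", "landscape_class",
    sprintf("width_m%02d", 1:12), sprintf("active_m%02d", 1:12))
}

cell_required_cols <- function() {
  c("cell_id", "lat_band", "climate_zone", "continent", "income_group",
    "country_id", sprintf("runoff_m%02d", 1:12))
}

write_delim_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

check_cols <- function(x, required, what) {
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(what, " table missing columns: ", paste(missing, collapse = ", "))
  x
}

#' Write and read the observation / reach / grid-cell tables
#'
#' Plain CSV with documented columns. Units: nutrient concentrations and DOC
#' in mg/L, DO in mg/L, chl_a in ug/L, water_temp in deg C, ch4_conc in
#' umol/L, diff_flux in mmol m-2 d-1, reach length and widths in m, loads in
#' kg/month, runoff in m3/month, population density in people km-2.
#'
#' @param x the table to write.
#' @param path CSV file path.
#' @return writers return `path` invisibly; readers return a validated
#'   `data.frame`.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_observations <- function(x, path) {
  check_cols(x, obs_required_cols(), "observation")
  write_delim_table(x, path)
}

#' @rdname table_io
#' @export
read_observations <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  check_cols(x, obs_required_cols(), "observation")
  if (any(x$month < 1 | x$month > 12)) stop("month out of 1..12")
  num <- c("TP", "NH4N", "TN", "NO3N", "chl_a")
  bad <- vapply(num, function(cc) any(x[[cc]] < 0, na.rm = TRUE), logical(1))
  if (any(bad))
    stop("negative concentrations in: ", paste(num[bad], collapse = ", "))
  x
}

#' @rdname table_io
#' @export
write_reaches <- function(x, path) {
  check_cols(x, reach_required_cols(), "reach")
  write_delim_table(x, path)
}

#' @rdname table_io
#' @export
read_reaches <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  check_cols(x, reach_required_cols(), "reach")
  if (any(x$length <= 0)) stop("reach length must be > 0")
  wcols <- sprintf("width_m%02d", 1:12)
  if (any(vapply(wcols, function(cc) any(x[[cc]] < 0), logical(1))))
    stop("negative reach width")
  for (cc in sprintf("active_m%02d", 1:12)) x[[cc]] <- as.logical(x[[cc]])
  x
}

#' @rdname table_io
#' @export
write_cells <- function(x, path) {
  check_cols(x, cell_required_cols(), "grid-cell")
  write_delim_table(x, path)
}

#' @rdname table_io
#' @export
read_cells <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  check_cols(x, cell_required_cols(), "grid-cell")
  rcols <- sprintf("runoff_m%02d", 1:12)
  if (any(vapply(rcols, function(cc) any(x[[cc]] <= 0), logical(1))))
    stop("runoff must be > 0 in every cell-month")
  x
}
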