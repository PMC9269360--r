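#' Station-year chlorophyll-a series
#'
#' One station-year of irregular satellite chlorophyll-a observations.
#' Observations are stored sorted by DOY; duplicate DOYs are rejected.
#'
#' @param station_id station label.
#' @param year calendar year.
#' @param doy integer day-of-year of each observation (1-366).
#' @param chl chlorophyll-a concentration (mg/m3), finite and non-negative.
#' @param masked_doys DOYs removed by ice masking (bookkeeping only).
#' @return an object of class `"chl_series"`.
#' @export
chl_series <- function(station_id, year, doy, chl, masked_doys = integer()) {
  stopifnot(length(doy) == length(chl))
  doy <- as.integer(doy)
  if (length(doy) > 0L) {
    if (anyNA(doy) || any(doy < 1L) || any(doy > 366L))
      stop_fmt("chl_series %s/%s: DOYs must be integers in 1-366", station_id, year)
    if (anyDuplicated(doy))
      stop_fmt("chl_series %s/%s: duplicate observation DOYs", station_id, year)
    o <- order(doy)
    doy <- doy[o]; chl <- as.numeric(chl)[o]
    if (anyNA(chl) || any(!is.finite(chl)) || any(chl < 0))
      stop_fmt("chl_series %s/%s: chlorophyll values must be finite and >= 0",
               station_id, year)
  } else chl <- numeric()
  structure(list(station_id = as.character(station_id),
                 year = as.integer(year),
                 observations = data.frame(doy = doy, chl = chl),
                 masked_doys = sort(unique(as.integer(masked_doys)))),
            class = "chl_series")
}

#' @export
print.chl_series <- function(x, ...) {
  cat(sprintf("<chl_series> %s %d: %d observations (DOY %s), %d ice-masked\n",
              x$station_id, x$year, nrow(x$observations),
              if (nrow(x$observations)) paste(range(x$observations$doy), collapse = "-") else "-",
              length(x$masked_doys)))
  invisible(x)
}

#' Station-year daily sea-ice concentration series
#'
#' Concentrations are kept on a DOY-indexed daily vector of length 366; days
#' absent from the input are `NA` (missing), never zero.
#'
#' @param station_id station label.
#' @param year calendar year.
#' @param doy integer DOYs with valid data.
#' @param ice_pct concentration (%) in \[0, 100\] for each `doy`.
#' @return an object of class `"ice_series"` with elements `station_id`,
#'   `year`, `conc` (length-366 numeric, `NA` = missing) and `coverage`
#'   (integer DOYs with data).
#' @export
ice_series <- function(station_id, year, doy, ice_pct) {
  stopifnot(length(doy) == length(ice_pct))
  doy <- as.integer(doy)
  ice_pct <- as.numeric(ice_pct)
  if (anyNA(doy) || any(doy < 1L) || any(doy > 366L))
    stop_fmt("ice_series %s/%s: DOYs must be integers in 1-366", station_id, year)
  if (anyDuplicated(doy))
    stop_fmt("ice_series %s/%s: duplicate DOYs", station_id, year)
  bad <- which(is.na(ice_pct) | ice_pct < 0 | ice_pct > 100)
  if (length(bad) > 0L)
    stop_fmt("ice_series %s/%s: concentration outside [0,100] at DOY %s",
             station_id, year, paste(doy[bad], collapse = ", "))
  conc <- rep(NA_real_, 366L)
  conc[doy] <- ice_pct
  structure(list(station_id = as.character(station_id),
                 year = as.integer(year),
                 conc = conc,
                 coverage = sort(doy)),
            class = "ice_series")
}

#' @export
print.ice_series <- function(x, ...) {
  cat(sprintf("<ice_series> %s %d: %d days with data (DOY %s)\n",
              x$station_id, x$year, length(x$coverage),
              if (length(x$coverage)) paste(range(x$coverage), collapse = "-") else "-"))
  invisible(x)
}

check_columns <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop_fmt("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
}

numeric_column <- function(df, col, path) {
  raw <- df[[col]]
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & is.na(x))
  if (length(bad) > 0L)
    stop_fmt("%s: non-numeric %s at line %d ('%s')",
             path, col, bad[1] + 1L, raw[bad[1]]) # +1 for the header line
  if (anyNA(x))
    stop_fmt("%s: missing %s at line %d", path, col, which(is.na(x))[1] + 1L)
  x
}

#' Read station-year chlorophyll-a series from CSV
#'
#' Expects header `station_id,year,doy,chl_mg_m3`. Rows are grouped into one
#' [chl_series()] per (station, year) and sorted by DOY; duplicate
#' (station, year, doy) rows are an error.
#'
#' @param path CSV file path.
#' @return named list of `chl_series`, keyed `"station:year"`.
#' @export
read_chl_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("station_id", "year", "doy", "chl_mg_m3"), path)
  df$year <- as.integer(numeric_column(df, "year", path))
  df$doy <- as.integer(numeric_column(df, "doy", path))
  df$chl_mg_m3 <- numeric_column(df, "chl_mg_m3", path)
  neg <- which(df$chl_mg_m3 < 0)
  if (length(neg) > 0L)
    stop_fmt("%s: negative chl_mg_m3 at line %d", path, neg[1] + 1L)
  key <- station_year_key(df$station_id, df$year)
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    if (anyDuplicated(g$doy))
      stop_fmt("%s: duplicate (station, year, doy) rows for %s %d (DOY %d)",
               path, g$station_id[1], g$year[1], g$doy[anyDuplicated(g$doy)])
    chl_series(g$station_id[1], g$year[1], g$doy, g$chl_mg_m3)
  })
  out
}

#' Read station-year sea-ice concentration series from CSV
#'
#' Expects header `station_id,year,doy,ice_pct`. DOYs absent from the file are
#' recorded as missing data, not as open water.
#'
#' @param path CSV file path.
#' @return named list of `ice_series`, keyed `"station:year"`.
#' @export
read_ice_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("station_id", "year", "doy", "ice_pct"), path)
  df$year <- as.integer(numeric_column(df, "year", path))
  df$doy <- as.integer(numeric_column(df, "doy", path))
  df$ice_pct <- numeric_column(df, "ice_pct", path)
  bad <- which(df$ice_pct < 0 | df$ice_pct > 100)
  if (length(bad) > 0L)
    stop_fmt("%s: ice_pct outside [0,100] at line %d (value %s)",
             path, bad[1] + 1L, df$ice_pct[bad[1]])
  key <- station_year_key(df$station_id, df$year)
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    ice_series(g$station_id[1], g$year[1], g$doy, g$ice_pct)
  })
}

#' Read shipboard pigment samples from CSV
#'
#' Expects header `station_id,year,doy,depth_m,chl_ug_L,pheo_ug_L`; one bottle
#' sample per row. Samples with chlorophyll-a + pheophytin equal to zero are
#' accepted but flagged `below_detection` (their proportion is undefined).
#' Surface samples are identified by `depth_m == 5` downstream.
#'
#' @param path CSV file path.
#' @return data.frame with the input columns plus logical `below_detection`.
#' @export
read_pigment_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("station_id", "year", "doy", "depth_m", "chl_ug_L", "pheo_ug_L"),
                path)
  df$year <- as.integer(numeric_column(df, "year", path))
  df$doy <- as.integer(numeric_column(df, "doy", path))
  df$depth_m <- numeric_column(df, "depth_m", path)
  df$chl_ug_L <- numeric_column(df, "chl_ug_L", path)
  df$pheo_ug_L <- numeric_column(df, "pheo_ug_L", path)
  bad <- which(df$depth_m <= 0)
  if (length(bad) > 0L)
    stop_fmt("%s: depth_m must be > 0 (line %d)", path, bad[1] + 1L)
  bad <- which(df$chl_ug_L < 0 | df$pheo_ug_L < 0)
  if (length(bad) > 0L)
    stop_fmt("%s: negative pigment value at line %d", path, bad[1] + 1L)
  df$below_detection <- (df$chl_ug_L + df$pheo_ug_L) == 0
  df
}

#' Write / read result tables with round-trip-exact numeric values
#'
#' Comma-delimited UTF-8 CSV with a mandatory header row. Numeric columns are
#' written with 17 significant digits so that re-reading reproduces the
#' doubles bit-for-bit.
#'
#' @param df data.frame to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 17, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
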