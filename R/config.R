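#' Analysis configuration
#'
#' Collects every fixed constant of the pipeline in one overridable list:
#' quality-control limits on the satellite series, the ice-masking and bloom
#' detection thresholds, the threshold-scan range, the sea-ice breakup and
#' open-water rules, and the test significance level.
#'
#' @param min_obs_per_year minimum satellite observations per station-year;
#'   series with fewer are not staged.
#' @param max_gap_days maximum tolerated gap (days) between consecutive
#'   observations, and between the seasonal window bounds and the nearest
#'   observation.
#' @param window_doys inclusive DOY pair of the extended sampling window that
#'   the series must resolve.
#' @param min_obs_in_window minimum observations inside `window_doys`.
#' @param ice_mask_pct observations on days with sea-ice concentration strictly
#'   above this percentage are masked out.
#' @param bloom_rise_min minimum rise (mg/m3) from a cycle's starting minimum
#'   to its peak for the cycle to count as a bloom.
#' @param threshold_range integer percentage range scanned during calibration.
#' @param breakup_pct sea-ice concentration (%) below which days count toward
#'   the breakup run.
#' @param breakup_run_days consecutive sub-threshold days defining breakup.
#' @param openwater_run_days_exclusive a spring zero-ice run must be strictly
#'   longer than this many days to mark a low-ice year.
#' @param amoc_penalty_factor multiplier on `log(n) * pooled variance` in the
#'   changepoint acceptance penalty.
#' @param surface_depth_m bottle depth (m) treated as the surface sample.
#' @param alpha two-sided significance level for group comparisons.
#' @param seed optional integer seed recorded for reproducibility.
#'
#' @return a named list with class `"run_config"`.
#' @seealso [read_run_config()] to load overrides from a YAML file.
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$window_doys
run_config <- function(min_obs_per_year = 6L,
                       max_gap_days = 25L,
                       window_doys = c(174L, 219L),
                       min_obs_in_window = 3L,
                       ice_mask_pct = 15,
                       bloom_rise_min = 0.5,
                       threshold_range = c(0L, 100L),
                       breakup_pct = 15,
                       breakup_run_days = 2L,
                       openwater_run_days_exclusive = 5L,
                       amoc_penalty_factor = 2,
                       surface_depth_m = 5,
                       alpha = 0.05,
                       seed = NULL) {
  stopifnot(length(window_doys) == 2L, window_doys[1] <= window_doys[2],
            length(threshold_range) == 2L,
            threshold_range[1] >= 0, threshold_range[2] <= 100,
            min_obs_per_year >= 1, max_gap_days >= 1,
            bloom_rise_min >= 0, alpha > 0, alpha < 1)
  cfg <- list(min_obs_per_year = as.integer(min_obs_per_year),
              max_gap_days = as.integer(max_gap_days),
              window_doys = as.integer(window_doys),
              min_obs_in_window = as.integer(min_obs_in_window),
              ice_mask_pct = ice_mask_pct,
              bloom_rise_min = bloom_rise_min,
              threshold_range = as.integer(threshold_range),
              breakup_pct = breakup_pct,
              breakup_run_days = as.integer(breakup_run_days),
              openwater_run_days_exclusive = as.integer(openwater_run_days_exclusive),
              amoc_penalty_factor = amoc_penalty_factor,
              surface_depth_m = surface_depth_m,
              alpha = alpha,
              seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Read configuration overrides from a YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults; unknown keys
#' are an error.
#'
#' @param path YAML file of `run_config` fields.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop_fmt("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Spring open-water window (March 1 to May 1) for a calendar year
#'
#' Computed from the calendar so leap years shift the window by one day:
#' DOY 60-121 in ordinary years, 61-122 in leap years.
#'
#' @param year calendar year.
#' @return inclusive integer DOY pair.
#' @export
#' @examples
#' openwater_window(2015) # 60 121
#' openwater_window(2016) # 61 122
openwater_window <- function(year) {
  stopifnot(is.numeric(year), length(year) == 1L)
  d1 <- as.POSIXlt(sprintf("%d-03-01", as.integer(year)), tz = "UTC")
  d2 <- as.POSIXlt(sprintf("%d-05-01", as.integer(year)), tz = "UTC")
  c(d1$yday + 1L, d2$yday + 1L)
}
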