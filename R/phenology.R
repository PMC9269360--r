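#' Remove chlorophyll observations on ice-affected days
#'
#' Observations falling on days whose sea-ice concentration is strictly
#' greater than `ice_mask_pct` are dropped and recorded in the series'
#' `masked_doys`. Days with missing ice data are retained: absence of an ice
#' estimate is not evidence of ice.
#'
#' @param series a [chl_series()].
#' @param ice the matching [ice_series()] (same station and year).
#' @param ice_mask_pct masking threshold, percent (default 15).
#' @return the masked `chl_series`.
#' @export
mask_ice_days <- function(series, ice, ice_mask_pct = 15) {
  stopifnot(inherits(series, "chl_series"), inherits(ice, "ice_series"))
  if (series$station_id != ice$station_id || series$year != ice$year)
    stop_fmt("mask_ice_days: series is %s/%d but ice is %s/%d",
             series$station_id, series$year, ice$station_id, ice$year)
  obs <- series$observations
  conc <- ice$conc[obs$doy]
  drop <- !is.na(conc) & conc > ice_mask_pct
  chl_series(series$station_id, series$year,
             obs$doy[!drop], obs$chl[!drop],
             masked_doys = c(series$masked_doys, obs$doy[drop]))
}

#' Quality-control a station-year chlorophyll series
#'
#' A series fails (and is not staged) when it has fewer than
#' `min_obs_per_year` observations, when any gap between consecutive
#' observations -- or between the extended sampling window's bounds and the
#' nearest observation -- exceeds `max_gap_days`, or when fewer than
#' `min_obs_in_window` observations fall inside `window_doys`. Masking is
#' assumed to have been applied already, so ice removal can cause a failure.
#'
#' @param series a [chl_series()] (after [mask_ice_days()]).
#' @param config a [run_config()].
#' @return list with `pass` (logical) and `rule` (failing rule name, or `NA`):
#'   one of `"min_observations"`, `"max_gap"`, `"window_min_obs"`.
#' @export
qc_series <- function(series, config = run_config()) {
  stopifnot(inherits(series, "chl_series"))
  d <- series$observations$doy
  if (length(d) < config$min_obs_per_year)
    return(list(pass = FALSE, rule = "min_observations"))
  w <- config$window_doys
  gaps <- c(max(0L, d[1] - w[1]), diff(d), max(0L, w[2] - d[length(d)]))
  if (any(gaps > config$max_gap_days))
    return(list(pass = FALSE, rule = "max_gap"))
  if (sum(d >= w[1] & d <= w[2]) < config$min_obs_in_window)
    return(list(pass = FALSE, rule = "window_min_obs"))
  list(pass = TRUE, rule = NA_character_)
}

#' Daily phenology curve
#'
#' Container for a smoothed, gap-free daily chlorophyll curve between the
#' first and last retained observation day. Mostly used by the synthetic
#' generators and tests; [fit_phenology_curve()] builds one from data.
#'
#' @param doy consecutive integer grid days.
#' @param chl curve value (mg/m3) on each grid day.
#' @param station_id,year provenance labels.
#' @return an object of class `"daily_curve"`.
#' @export
daily_curve <- function(doy, chl, station_id = "", year = NA_integer_) {
  doy <- as.integer(doy)
  stopifnot(length(doy) == length(chl), length(doy) >= 1L)
  if (!all(diff(doy) == 1L))
    stop_fmt("daily_curve: grid must be consecutive days")
  structure(list(station_id = as.character(station_id),
                 year = as.integer(year),
                 doy = doy, chl = as.numeric(chl)),
            class = "daily_curve")
}

#' @export
print.daily_curve <- function(x, ...) {
  cat(sprintf("<daily_curve> %s %s: DOY %d-%d, chl %.3g-%.3g mg/m3\n",
              x$station_id, x$year, x$doy[1], x$doy[length(x$doy)],
              min(x$chl), max(x$chl)))
  invisible(x)
}

#' Smooth an irregular series into a daily phenology curve
#'
#' A tricube-weighted locally weighted linear regression (a single-pass
#' scatterplot smoother) is evaluated at every observation day, and the
#' smoothed points are joined by linear interpolation onto the daily grid.
#' The curve never extends beyond the first and last observation. Robustness
#' reweighting is deliberately off: iterating would treat genuine bloom peaks
#' as outliers and flatten them.
#'
#' @param series a [chl_series()] that passed [qc_series()].
#' @param span smoothing span in *points* per local fit; default
#'   `max(7, ceiling(0.3 * n))`, chosen to stay stable at the typical density
#'   of roughly 27 cloud-free observations per year.
#' @return a [daily_curve()].
#' @export
fit_phenology_curve <- function(series, span = NULL) {
  stopifnot(inherits(series, "chl_series"))
  obs <- series$observations
  n <- nrow(obs)
  if (n < 3L)
    stop_fmt("fit_phenology_curve: need at least 3 observations, got %d", n)
  span_pts <- if (is.null(span)) max(7L, ceiling(0.3 * n)) else as.integer(span)
  if (span_pts < 3L)
    stop_fmt("fit_phenology_curve: span of %d points gives under-determined local fits",
             span_pts)
  span_pts <- min(span_pts, n)
  sm <- stats::lowess(obs$doy, obs$chl, f = span_pts / n, iter = 0L)
  grid <- seq(obs$doy[1], obs$doy[n])
  vals <- stats::approx(sm$x, sm$y, xout = grid)$y
  daily_curve(grid, vals, series$station_id, series$year)
}

# segment boundaries of a daily vector: first index, interior strict local
# minima (plateaus collapsed to their first day), last index
segment_bounds <- function(v) {
  n <- length(v)
  if (n < 3L) return(c(1L, n))
  r <- rle(v)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  ismin <- logical(k)
  if (k >= 3L)
    for (j in 2:(k - 1L))
      ismin[j] <- r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L]
  unique(c(1L, starts[ismin], n))
}

#' Detect bloom cycles on a daily curve
#'
#' The curve is segmented at strict local minima (a minimum plateau counts
#' from its first day). A segment becomes a bloom cycle when its peak rises at
#' least `bloom_rise_min` above the starting minimum: t1 is the preceding
#' minimum, t2 the earliest day attaining the segment maximum, t3 the
#' following minimum (or the last grid day, flagged `truncated_end` when the
#' curve is still above its starting level there). A sub-threshold segment
#' whose shared minimum with the preceding bloom stays above that bloom's
#' starting chlorophyll is absorbed into it (a continuation of the large
#' cycle); otherwise it contributes no cycle.
#'
#' @param curve a [daily_curve()].
#' @param bloom_rise_min minimum chlorophyll rise (mg/m3, default 0.5).
#' @return data.frame of class `"bloom_cycles"` with columns `t1`, `t2`, `t3`
#'   (DOY), `chl_t1`, `chl_t2`, `chl_t3`, `amplitude`, `truncated_end`,
#'   ordered by `t1`; attribute `doy_range` records the curve's grid extent.
#' @export
detect_bloom_cycles <- function(curve, bloom_rise_min = 0.5) {
  stopifnot(inherits(curve, "daily_curve"))
  v <- curve$chl
  d <- curve$doy
  n <- length(v)
  bounds <- segment_bounds(v)
  cycles <- list()
  cur <- NULL # indices c(a, b) of the open bloom
  if (length(bounds) >= 2L) {
    for (i in seq_len(length(bounds) - 1L)) {
      a <- bounds[i]; b <- bounds[i + 1L]
      peak <- a - 1L + which.max(v[a:b])
      if (v[peak] - v[a] >= bloom_rise_min) {
        if (!is.null(cur)) cycles[[length(cycles) + 1L]] <- cur
        cur <- c(a, b)
      } else if (!is.null(cur) && cur[2] == a && v[a] > v[cur[1]]) {
        cur[2] <- b # continuation: intervening minimum never fell to baseline
      } # else: minor variability, no cycle
    }
  }
  if (!is.null(cur)) cycles[[length(cycles) + 1L]] <- cur
  rows <- lapply(cycles, function(ab) {
    a <- ab[1]; b <- ab[2]
    peak <- a - 1L + which.max(v[a:b])
    data.frame(t1 = d[a], t2 = d[peak], t3 = d[b],
               chl_t1 = v[a], chl_t2 = v[peak], chl_t3 = v[b],
               amplitude = v[peak] - v[a],
               truncated_end = (b == n && v[b] > v[a]))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t1 = integer(), t2 = integer(), t3 = integer(),
               chl_t1 = numeric(), chl_t2 = numeric(), chl_t3 = numeric(),
               amplitude = numeric(), truncated_end = logical())
  attr(out, "doy_range") <- c(d[1], d[n])
  class(out) <- c("bloom_cycles", "data.frame")
  out
}

#' Classify the bloom stage at a sampling day
#'
#' Early Bloom (`"EB"`) when the day lies between a cycle's start and peak
#' inclusive, Post Bloom (`"PB"`) when strictly after the peak up to and
#' including the end, and No Bloom (`"NB"`) anywhere on the grid outside all
#' cycles. A day outside the curve's observed extent is an error, distinct
#' from No Bloom: the curve says nothing there.
#'
#' @param cycles a `"bloom_cycles"` table from [detect_bloom_cycles()].
#' @param sample_doy integer day-of-year of sampling.
#' @return `"EB"`, `"PB"`, or `"NB"`.
#' @export
classify_stage <- function(cycles, sample_doy) {
  stopifnot(inherits(cycles, "bloom_cycles"), length(sample_doy) == 1L)
  rng <- attr(cycles, "doy_range")
  if (!is.null(rng) && (sample_doy < rng[1] || sample_doy > rng[2]))
    stop_fmt("classify_stage: DOY %d is outside the curve coverage (%d-%d)",
             sample_doy, rng[1], rng[2])
  for (i in seq_len(nrow(cycles))) {
    if (sample_doy >= cycles$t1[i] && sample_doy <= cycles$t2[i]) return("EB")
    if (sample_doy > cycles$t2[i] && sample_doy <= cycles$t3[i]) return("PB")
  }
  "NB"
}
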