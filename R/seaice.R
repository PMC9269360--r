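#' Sea-ice breakup date of a station-year
#'
#' Breakup is the first day of the earliest run of `run_days` consecutive days
#' with concentration strictly below `breakup_pct`, searched strictly after
#' the last day attaining the annual maximum concentration (so open-water
#' episodes punched into the winter pack cannot register as breakup). If the
#' concentration never reaches `breakup_pct` at any time -- winter ice never
#' formed -- there is no breakup to date and `no_ice_flag` is set. Missing
#' days break runs.
#'
#' @param ice an [ice_series()].
#' @param breakup_pct concentration threshold, percent (default 15).
#' @param run_days required consecutive sub-threshold days (default 2).
#' @return list of class `"breakup_result"`: `station_id`, `year`,
#'   `breakup_doy` (integer or `NA`), `no_ice_flag`.
#' @export
breakup_doy <- function(ice, breakup_pct = 15, run_days = 2L) {
  stopifnot(inherits(ice, "ice_series"), run_days >= 1L)
  conc <- ice$conc
  if (all(is.na(conc)))
    stop_fmt("breakup_doy: %s/%d has no valid ice data", ice$station_id, ice$year)
  mx <- max(conc, na.rm = TRUE)
  if (mx < breakup_pct)
    return(structure(list(station_id = ice$station_id, year = ice$year,
                          breakup_doy = NA_integer_, no_ice_flag = TRUE),
                     class = "breakup_result"))
  last_max <- max(which(conc == mx))
  below <- !is.na(conc) & conc < breakup_pct
  below[seq_len(last_max)] <- FALSE
  start <- first_run_start(below, run_days)
  structure(list(station_id = ice$station_id, year = ice$year,
                 breakup_doy = start, no_ice_flag = FALSE),
            class = "breakup_result")
}

#' Ice-year class from spring open-water runs
#'
#' A station-year is a low-ice year when some run of *strictly more than*
#' `run_days_exclusive` consecutive days within the March 1 - May 1 window has
#' zero sea-ice concentration (zero meaning the value rounds to 0 at integer
#' percent, absorbing sub-0.5% retrieval noise). High ice is the default;
#' missing days inside the window break runs.
#'
#' @param ice an [ice_series()].
#' @param window inclusive DOY pair; defaults to the calendar March 1 - May 1
#'   window of the series' year ([openwater_window()]).
#' @param run_days_exclusive run length that must be exceeded (default 5,
#'   i.e. 6 or more zero days flag a low-ice year).
#' @return `"HIGH"` or `"LOW"`.
#' @export
concentration_ice_class <- function(ice, window = NULL, run_days_exclusive = 5L) {
  stopifnot(inherits(ice, "ice_series"))
  window <- window %||% openwater_window(ice$year)
  days <- seq(window[1], window[2])
  conc <- ice$conc[days]
  zero <- !is.na(conc) & round(conc) == 0
  if (max_run_length(zero) > run_days_exclusive) "LOW" else "HIGH"
}

#' At-most-one-change changepoint in a breakup-date sequence
#'
#' Exhaustive scan over single mean-shift splits (minimum segment length 2)
#' minimizing the total within-segment sum of squared deviations. The best
#' split is accepted only when its SSE reduction over the no-change model
#' exceeds a variance-scaled penalty, `penalty_factor * log(n) * pooled
#' variance` (pooled variance = best split SSE / (n - 2)); otherwise the
#' sequence is treated as changeless. The high/low ice DOY threshold is the
#' midpoint of the two segment means (or the overall mean without a split).
#'
#' @param breakup_doys numeric breakup DOYs for one station, in year order;
#'   `NA` entries (years without a breakup) are dropped before fitting.
#' @param min_segment minimum observations per segment (default 2).
#' @param penalty_factor penalty multiplier (default 2).
#' @return list of class `"amoc_changepoint"`: `split_index` (last index of
#'   the first segment, or `NA`), `pre_mean`, `post_mean`, `doy_threshold`,
#'   `n_used`, `sse_null`, `sse_split`, `penalty`.
#' @export
#' @examples
#' amoc_changepoint(c(150, 148, 152, 110, 112, 108))$doy_threshold # 130
amoc_changepoint <- function(breakup_doys, min_segment = 2L, penalty_factor = 2) {
  x <- as.numeric(breakup_doys)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L * min_segment)
    stop_fmt("amoc_changepoint: need at least %d years with breakup dates, got %d",
             2L * min_segment, n)
  sse <- function(v) sum((v - mean(v))^2)
  sse_null <- sse(x)
  splits <- seq(min_segment, n - min_segment)
  sses <- vapply(splits, function(s) sse(x[1:s]) + sse(x[(s + 1):n]), 0)
  best <- which.min(sses)
  split <- splits[best]
  sse_split <- sses[best]
  pooled_var <- sse_split / (n - 2L)
  penalty <- penalty_factor * log(n) * pooled_var
  if ((sse_null - sse_split) > penalty) {
    pre <- mean(x[1:split]); post <- mean(x[(split + 1):n])
    res <- list(split_index = split, pre_mean = pre, post_mean = post,
                doy_threshold = (pre + post) / 2)
  } else {
    res <- list(split_index = NA_integer_, pre_mean = NA_real_,
                post_mean = NA_real_, doy_threshold = mean(x))
  }
  structure(c(res, list(n_used = n, sse_null = sse_null,
                        sse_split = sse_split, penalty = penalty)),
            class = "amoc_changepoint")
}

#' @export
print.amoc_changepoint <- function(x, ...) {
  if (is.na(x$split_index))
    cat(sprintf("<amoc_changepoint> no accepted change (n=%d); threshold DOY %.1f\n",
                x$n_used, x$doy_threshold))
  else
    cat(sprintf("<amoc_changepoint> split after %d: means %.1f -> %.1f, threshold DOY %.1f\n",
                x$split_index, x$pre_mean, x$post_mean, x$doy_threshold))
  invisible(x)
}

#' Ice-year class from the breakup date
#'
#' Low ice when breakup precedes the changepoint-derived DOY threshold, or
#' when winter ice never formed (no breakup exists: the low-ice extreme).
#' High ice otherwise, including years whose ice formed but never broke up.
#'
#' @param result a `"breakup_result"` from [breakup_doy()].
#' @param doy_threshold DOY threshold from [amoc_changepoint()].
#' @return `"HIGH"` or `"LOW"`.
#' @export
breakup_ice_class <- function(result, doy_threshold) {
  stopifnot(inherits(result, "breakup_result"), length(doy_threshold) == 1L)
  if (isTRUE(result$no_ice_flag)) return("LOW")
  if (!is.na(result$breakup_doy) && result$breakup_doy < doy_threshold) "LOW" else "HIGH"
}
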