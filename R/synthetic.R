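#' Specification of a synthetic chlorophyll station-year
#'
#' Describes the noiseless truth (a baseline plus Gaussian bloom pulses) and
#' the observation process (i.i.d. per-day cloud loss, multiplicative
#' lognormal noise) used by [gen_chl_series()]. Defaults represent the
#' sampling regime the analysis is built for: an optical season of DOY
#' 121-273 and a cloud retention giving roughly 27 usable observations per
#' year, with a large spring bloom and a smaller mid-summer pulse.
#'
#' @param baseline background chlorophyll (mg/m3).
#' @param pulses list of `c(peak_doy, amplitude, width)` triplets; each pulse
#'   is `amplitude * exp(-0.5 ((d - peak)/width)^2)` (width = Gaussian sigma,
#'   days).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   observation noise (mean-one).
#' @param cloud_prob per-day probability that an observation is lost to cloud.
#' @param obs_window inclusive DOY pair over which observations can occur.
#' @param asymmetry ratio of the falling to the rising width of each pulse
#'   (1 = symmetric).
#' @param seed optional integer seed.
#' @return list of class `"bloom_spec"`.
#' @export
bloom_spec <- function(baseline = 0.3,
                       pulses = list(c(peak_doy = 150, amplitude = 5, width = 10),
                                     c(peak_doy = 200, amplitude = 1.5, width = 8)),
                       noise_cv = 0.15,
                       cloud_prob = 0.82,
                       obs_window = c(121L, 273L),
                       asymmetry = 1,
                       seed = NULL) {
  stopifnot(baseline >= 0, noise_cv >= 0,
            cloud_prob >= 0, cloud_prob < 1, asymmetry > 0,
            length(obs_window) == 2L, obs_window[1] < obs_window[2])
  for (p in pulses) {
    stopifnot(length(p) == 3L)
    if (p[2] <= 0 || p[3] <= 0)
      stop_fmt("bloom_spec: pulse amplitude and width must be > 0")
  }
  structure(list(baseline = baseline, pulses = pulses, noise_cv = noise_cv,
                 cloud_prob = cloud_prob, obs_window = as.integer(obs_window),
                 asymmetry = asymmetry, seed = seed),
            class = "bloom_spec")
}

pulse_curve <- function(d, spec) {
  v <- rep(spec$baseline, length(d))
  for (p in spec$pulses) {
    w <- ifelse(d <= p[1], p[3], p[3] * spec$asymmetry)
    v <- v + p[2] * exp(-0.5 * ((d - p[1]) / w)^2)
  }
  v
}

#' Generate a cloud-thinned chlorophyll series and its generating truth
#'
#' Builds the noiseless daily truth curve over the observation window, records
#' the true bloom cycles ([detect_bloom_cycles()] applied to the truth), then
#' thins days by i.i.d. cloud loss and perturbs the retained observations
#' with mean-one multiplicative lognormal noise. If every day clouds out, the
#' draw is retried (up to 5 attempts, with a message).
#'
#' @param spec a [bloom_spec()].
#' @param station_id,year labels for the generated series.
#' @return list: `series` (a [chl_series()]) and `truth` (list with the
#'   noiseless `curve` and its `cycles`).
#' @export
gen_chl_series <- function(spec, station_id = "SYN", year = 2015L) {
  stopifnot(inherits(spec, "bloom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  d <- seq(spec$obs_window[1], spec$obs_window[2])
  truth_v <- pulse_curve(d, spec)
  truth_curve <- daily_curve(d, truth_v, station_id, year)
  truth_cycles <- detect_bloom_cycles(truth_curve)
  sigma <- sqrt(log(1 + spec$noise_cv^2))
  for (attempt in 1:5) {
    keep <- stats::runif(length(d)) > spec$cloud_prob
    if (any(keep)) break
    if (attempt == 5L)
      stop_fmt("gen_chl_series: all days clouded out after 5 attempts")
    message("gen_chl_series: all days clouded out, redrawing (attempt ",
            attempt + 1L, ")")
  }
  noise <- exp(stats::rnorm(sum(keep), mean = -sigma^2 / 2, sd = sigma))
  list(series = chl_series(station_id, year, d[keep], truth_v[keep] * noise),
       truth = list(curve = truth_curve, cycles = truth_cycles))
}

#' Specification of a synthetic sea-ice station-year
#'
#' A winter plateau at `winter_max_pct` that declines logistically so that the
#' first two-day run below 15% concentration starts exactly at
#' `breakup_doy_true`, with optional zero-concentration open-water episodes
#' punched into the winter pack.
#'
#' @param winter_max_pct winter plateau concentration, percent in (15, 100\].
#' @param breakup_doy_true DOY at which the detected breakup run should start.
#' @param decline_width span (days) of the logistic melt decline.
#' @param openwater_episodes list of `c(start_doy, length)` zero-ice runs;
#'   episodes must end before the decline begins.
#' @param seed optional integer seed (the generator itself is deterministic;
#'   kept for interface symmetry).
#' @return list of class `"ice_spec"`.
#' @export
ice_spec <- function(winter_max_pct = 95,
                     breakup_doy_true = 120L,
                     decline_width = 12,
                     openwater_episodes = list(),
                     seed = NULL) {
  stopifnot(winter_max_pct > 15, winter_max_pct <= 100,
            breakup_doy_true > 1, breakup_doy_true <= 300,
            decline_width > 0)
  for (e in openwater_episodes) {
    stopifnot(length(e) == 2L)
    if (e[1] < 1 || e[2] < 1 || e[1] + e[2] - 1 > 365)
      stop_fmt("ice_spec: episode outside the series span")
  }
  structure(list(winter_max_pct = winter_max_pct,
                 breakup_doy_true = as.integer(breakup_doy_true),
                 decline_width = decline_width,
                 openwater_episodes = openwater_episodes,
                 seed = seed),
            class = "ice_spec")
}

#' Generate a seasonal sea-ice concentration series
#'
#' @param spec an [ice_spec()].
#' @param station_id,year labels for the generated series.
#' @return an [ice_series()] covering DOY 1-365.
#' @export
gen_ice_series <- function(spec, station_id = "SYN", year = 2015L) {
  stopifnot(inherits(spec, "ice_spec"))
  k <- spec$decline_width / 4
  # place the 15% crossing half a day before breakup so the first whole day
  # below threshold is exactly breakup_doy_true
  c0 <- spec$breakup_doy_true - 0.5 - k * log(spec$winter_max_pct / 15 - 1)
  plateau_end <- floor(c0 - 3 * k)
  if (plateau_end < 1)
    stop_fmt("gen_ice_series: breakup too early for the requested decline width")
  d <- 1:365
  conc <- ifelse(d <= plateau_end, spec$winter_max_pct,
                 spec$winter_max_pct / (1 + exp((d - c0) / k)))
  for (e in spec$openwater_episodes) {
    if (e[1] + e[2] - 1 >= plateau_end)
      stop_fmt("ice_spec: open-water episode (%d, %d days) overlaps the melt decline",
               e[1], e[2])
    conc[seq(e[1], e[1] + e[2] - 1)] <- 0
  }
  conc <- pmin(100, pmax(0, conc))
  ice_series(station_id, year, d, conc)
}

#' Specification of synthetic pigment profiles
#'
#' Surface pheophytin proportions are drawn below the generating class
#' boundary for Early Bloom station-years and above it for Post Bloom;
#' deeper samples drift toward higher proportions (pheopigment accumulation
#' at depth). With `anchors` on, dataset generators insert one EB sample just
#' below the boundary and one PB sample exactly at it, making the boundary
#' the unique perfectly separating integer threshold.
#'
#' @param true_boundary proportion separating the EB and PB regimes.
#' @param eb_range,pb_range uniform sampling intervals for surface proportions
#'   of EB and PB station-years; `eb_range` must lie entirely below
#'   `true_boundary`, which must not exceed the lower bound of `pb_range`.
#' @param depths bottle depths (m) of each profile.
#' @param depth_drift mean increase in proportion per metre of depth.
#' @param total_meanlog,total_sdlog lognormal parameters of the combined
#'   pigment concentration (ug/L) at each depth.
#' @param anchors insert the boundary-adjacent pair in generated datasets.
#' @param seed optional integer seed.
#' @return list of class `"pigment_spec"`.
#' @export
pigment_spec <- function(true_boundary = 0.28,
                         eb_range = c(0.10, 0.27),
                         pb_range = c(0.29, 0.60),
                         depths = c(5, 15, 25, 35, 50),
                         depth_drift = 0.004,
                         total_meanlog = log(5),
                         total_sdlog = 0.4,
                         anchors = TRUE,
                         seed = NULL) {
  stopifnot(true_boundary > 0, true_boundary < 1,
            length(eb_range) == 2L, length(pb_range) == 2L,
            eb_range[1] < eb_range[2], pb_range[1] <= pb_range[2],
            eb_range[2] < true_boundary, true_boundary <= pb_range[1],
            all(depths > 0), depth_drift >= 0)
  structure(list(true_boundary = true_boundary, eb_range = eb_range,
                 pb_range = pb_range, depths = depths,
                 depth_drift = depth_drift, total_meanlog = total_meanlog,
                 total_sdlog = total_sdlog, anchors = anchors, seed = seed),
            class = "pigment_spec")
}

#' Generate one station-year pigment profile
#'
#' @param spec a [pigment_spec()].
#' @param stage `"EB"` or `"PB"`: which surface-proportion regime to draw
#'   from (ignored when `surface_proportion` is supplied).
#' @param station_id,year,doy sample labels.
#' @param surface_proportion optional explicit surface proportion.
#' @return data.frame of bottle samples (`station_id`, `year`, `doy`,
#'   `depth_m`, `chl_ug_L`, `pheo_ug_L`, `below_detection`).
#' @export
gen_pigment_samples <- function(spec, stage = c("EB", "PB"),
                                station_id = "SYN", year = 2015L, doy = 196L,
                                surface_proportion = NULL) {
  stopifnot(inherits(spec, "pigment_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(surface_proportion)) {
    stage <- match.arg(stage)
    rng <- if (stage == "EB") spec$eb_range else spec$pb_range
    p_surf <- stats::runif(1, rng[1], rng[2])
  } else p_surf <- surface_proportion
  depths <- sort(spec$depths)
  drift <- spec$depth_drift * (depths - depths[1]) *
    stats::runif(length(depths), 0.5, 1.5)
  p <- pmin(0.95, p_surf + drift)
  total <- stats::rlnorm(length(depths), spec$total_meanlog, spec$total_sdlog)
  data.frame(station_id = station_id, year = as.integer(year),
             doy = as.integer(doy), depth_m = depths,
             chl_ug_L = total * (1 - p), pheo_ug_L = total * p,
             below_detection = FALSE)
}

#' Generate a matched field/satellite calibration dataset
#'
#' Assigns each synthetic station-year a satellite stage label (an EB/PB mix,
#' by default 23:5 in 28 as in the study's matched set), draws a surface
#' pheophytin proportion from the stage's regime, and builds the full
#' pigment profiles. With anchors on, the first EB station-year is placed at
#' `true_boundary - 0.001` and the first PB exactly at `true_boundary`, so
#' the boundary (x100) is the only integer threshold classifying both
#' correctly under the strict-less rule.
#'
#' @param n_station_years number of matched station-years (>= 4).
#' @param spec a [pigment_spec()].
#' @param seed optional integer seed.
#' @param eb_fraction fraction of station-years labelled satellite EB.
#' @return list: `pairs` (station_id, year, satellite_stage, proportion) and
#'   `samples` (the bottle table).
#' @export
gen_calibration_dataset <- function(n_station_years = 28L,
                                    spec = pigment_spec(),
                                    seed = NULL,
                                    eb_fraction = 23 / 28) {
  stopifnot(n_station_years >= 4L)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_station_years)
  n_eb <- min(n - 1L, max(1L, round(eb_fraction * n)))
  labels <- c(rep("EB", n_eb), rep("PB", n - n_eb))
  props <- numeric(n)
  for (i in seq_len(n)) {
    rng <- if (labels[i] == "EB") spec$eb_range else spec$pb_range
    props[i] <- stats::runif(1, rng[1], rng[2])
  }
  if (isTRUE(spec$anchors)) {
    props[which(labels == "EB")[1]] <- spec$true_boundary - 0.001
    props[which(labels == "PB")[1]] <- spec$true_boundary
  }
  station <- sprintf("SY%02d", seq_len(n))
  year <- 2013L + (seq_len(n) - 1L) %% 7L
  samples <- do.call(rbind, lapply(seq_len(n), function(i) {
    gen_pigment_samples(spec, station_id = station[i], year = year[i],
                        surface_proportion = props[i])
  }))
  list(pairs = data.frame(station_id = station, year = year,
                          satellite_stage = labels, proportion = props),
       samples = samples)
}

#' Deterministic replica of the published matched-classification table
#'
#' Encodes the 28 matched station-years behind the published field-vs-satellite
#' error matrix -- 16 agreeing EB, 7 satellite-EB field-PB (proportions spread
#' over 29-61%, the range reported for those misclassifications), and 5
#' agreeing PB -- with surface proportions that reproduce the matrix exactly
#' at the 28% threshold. The underlying raw proportions were never published,
#' so this replica fixes the matrix cells, not the full threshold scan.
#'
#' @return list: `pairs` (with `satellite_stage` and `proportion`) and
#'   `samples` (surface bottle rows, combined pigment 10 ug/L).
#' @export
table1_dataset <- function() {
  props <- c(seq(0.05, 0.27, length.out = 16),
             seq(0.29, 0.61, length.out = 7),
             seq(0.30, 0.60, length.out = 5))
  sat <- c(rep("EB", 16), rep("EB", 7), rep("PB", 5))
  n <- length(props)
  station <- sprintf("T%02d", seq_len(n))
  year <- 2013L + (seq_len(n) - 1L) %% 7L
  list(pairs = data.frame(station_id = station, year = year,
                          satellite_stage = sat, proportion = props),
       samples = data.frame(station_id = station, year = year, doy = 196L,
                            depth_m = 5, chl_ug_L = 10 * (1 - props),
                            pheo_ug_L = 10 * props, below_detection = FALSE))
}

#' Generate a full multi-station, multi-year study dataset
#'
#' Emulates the observing design of the source analysis: 13 stations sampled
#' each July over seven years, with low-ice regimes in the final two years
#' (including two station-years where winter ice never forms). Ice series,
#' cloud-thinned chlorophyll series tied to the breakup timing, and pigment
#' profiles whose surface proportions differ between the ice regimes (low ice
#' mean 0.25, SD 0.07; high ice mean 0.34, SD 0.15) are produced together.
#'
#' @param seed optional integer seed.
#' @param stations station labels.
#' @param years calendar years.
#' @param low_ice_years years generated under the low-ice regime.
#' @return list: `chl` and `ice` (named lists keyed `"station:year"`),
#'   `pigments` (bottle table), `meta` (per station-year regime and true
#'   breakup DOY).
#' @export
gen_full_study <- function(seed = NULL,
                           stations = c(paste0("SLIP-", 1:5), "BCL-6A", "BCL-6C",
                                        paste0("UTBS-", 1:5), "DBO2.7"),
                           years = 2013:2019,
                           low_ice_years = c(2018L, 2019L)) {
  if (!is.null(seed)) set.seed(seed)
  chl <- list(); ice <- list(); pig <- list(); meta <- list()
  pspec <- pigment_spec()
  for (st in stations) for (yr in years) {
    key <- station_year_key(st, yr)
    low <- yr %in% low_ice_years
    no_ice <- (yr == 2018L && st %in% c("SLIP-1", "SLIP-2"))
    if (no_ice) {
      bk <- NA_integer_
      ice[[key]] <- ice_series(st, yr, 1:365, rep(0, 365))
    } else if (low) {
      bk <- round(min(125, max(95, stats::rnorm(1, 105, 6))))
      eps <- list(c(round(stats::runif(1, 61, 66)), round(stats::runif(1, 7, 10))))
      ice[[key]] <- gen_ice_series(
        ice_spec(breakup_doy_true = bk, openwater_episodes = eps), st, yr)
    } else {
      bk <- round(min(175, max(130, stats::rnorm(1, 150, 7))))
      ice[[key]] <- gen_ice_series(ice_spec(breakup_doy_true = bk), st, yr)
    }
    # high-ice springs seed an early bloom that has matured by the July
    # cruise; low-ice springs delay the bloom so July sampling catches it
    # still growing
    peak1 <- stats::rnorm(1, if (low) 198 else 172, 6)
    bspec <- bloom_spec(pulses = list(
      c(peak1, stats::runif(1, 2, 6), stats::runif(1, 9, 13))))
    g <- gen_chl_series(bspec, st, yr)
    chl[[key]] <- g$series
    sdoy <- sample(194:199, 1)
    true_stage <- classify_stage(g$truth$cycles, sdoy)
    # pigments follow the bloom stage actually sampled: growing blooms are
    # pheophytin-poor, mature or ended blooms pheophytin-rich
    rng <- if (true_stage == "EB") pspec$eb_range else pspec$pb_range
    pig[[key]] <- gen_pigment_samples(pspec, station_id = st, year = yr,
                                      doy = sdoy,
                                      surface_proportion = stats::runif(1, rng[1], rng[2]))
    meta[[key]] <- data.frame(station_id = st, year = yr,
                              regime = if (low) "LOW" else "HIGH",
                              breakup_true = bk, true_stage = true_stage)
  }
  list(chl = chl, ice = ice,
       pigments = do.call(rbind, c(pig, list(make.row.names = FALSE))),
       meta = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}
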