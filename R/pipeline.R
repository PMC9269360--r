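series_key <- function(x) station_year_key(x$station_id, x$year)

surface_proportion_of <- function(samples, surface_depth_m = 5) {
  s <- samples[samples$depth_m == surface_depth_m & !samples$below_detection, ,
               drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  # pool pigment mass across replicate surface bottles
  pheophytin_proportion(sum(s$chl_ug_L), sum(s$pheo_ug_L))
}

profile_proportion_of <- function(samples) {
  s <- samples[!samples$below_detection, , drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  # replicate bottles at one depth are averaged before integrating
  chl <- tapply(s$chl_ug_L, s$depth_m, mean)
  pheo <- tapply(s$pheo_ug_L, s$depth_m, mean)
  d <- as.numeric(names(chl))
  depth_integrated_proportion(d, as.numeric(chl), as.numeric(pheo))$proportion
}

#' Calibrate the pheophytin threshold against satellite bloom stages
#'
#' For every station-year present in both the chlorophyll list and the
#' pigment table, the satellite series is ice-masked, quality-controlled,
#' smoothed into a daily curve, segmented into bloom cycles, and staged at
#' the field sampling day. Station-years failing QC (or sampled outside the
#' curve's coverage) are staged `"NAN"` and logged with the failing rule.
#' Satellite No-Bloom and NAN station-years are excluded, and the remaining
#' matched pairs drive the exhaustive threshold scan and its error matrix.
#'
#' @param chl named list of [chl_series()] (e.g. from [read_chl_series()]).
#' @param ice named list of [ice_series()], matched by station and year;
#'   station-years without ice data are simply not masked.
#' @param pigments pigment sample table ([read_pigment_samples()]).
#' @param config a [run_config()].
#' @param span optional smoothing span override (points).
#' @return list of class `"calibration_report"`: `stages` (per station-year
#'   satellite stage, field proportion, field stage at the selected
#'   threshold), `cycles` (per-bloom t1/t2/t3 table), `scan`,
#'   `selected_threshold`, `error_matrix`, `metrics`, `excluded`.
#' @export
run_calibration <- function(chl, ice, pigments, config = run_config(),
                            span = NULL) {
  ice_keys <- vapply(ice, series_key, "")
  pig_keys <- station_year_key(pigments$station_id, pigments$year)
  stages <- list(); cycles <- list(); excluded <- list()
  for (s in chl) {
    key <- series_key(s)
    pig_sub <- pigments[pig_keys == key, , drop = FALSE]
    if (nrow(pig_sub) == 0L) next # no field data: nothing to match
    prop <- surface_proportion_of(pig_sub, config$surface_depth_m)
    sample_doy <- pig_sub$doy[1]
    im <- which(ice_keys == key)
    if (length(im) > 0L)
      s <- mask_ice_days(s, ice[[im[1]]], config$ice_mask_pct)
    qc <- qc_series(s, config)
    if (!qc$pass) {
      message(sprintf("excluding %s %d: failed QC rule '%s'",
                      s$station_id, s$year, qc$rule))
      excluded[[key]] <- data.frame(station_id = s$station_id, year = s$year,
                                    rule = qc$rule)
      stage <- "NAN"
    } else {
      curve <- fit_phenology_curve(s, span)
      cyc <- detect_bloom_cycles(curve, config$bloom_rise_min)
      if (nrow(cyc) > 0L)
        cycles[[key]] <- cbind(data.frame(station_id = s$station_id,
                                          year = s$year), as.data.frame(cyc))
      stage <- tryCatch(classify_stage(cyc, sample_doy), error = function(e) {
        message(sprintf("excluding %s %d: sampling DOY %d outside curve coverage",
                        s$station_id, s$year, sample_doy))
        excluded[[key]] <<- data.frame(station_id = s$station_id,
                                       year = s$year, rule = "out_of_coverage")
        "NAN"
      })
    }
    stages[[key]] <- data.frame(station_id = s$station_id, year = s$year,
                                sample_doy = sample_doy,
                                satellite_stage = stage,
                                field_proportion = prop)
  }
  stages <- rbind_all(stages)
  if (is.null(stages) || nrow(stages) == 0L)
    stop_fmt("run_calibration: no station-years with both satellite and field data")
  usable <- stages$satellite_stage %in% c("EB", "PB") &
    !is.na(stages$field_proportion)
  if (!any(usable))
    stop_fmt(paste("run_calibration: empty calibration -- no station-years with",
                   "both a satellite EB/PB stage and a surface proportion"))
  scan <- scan_thresholds(stages$field_proportion[usable],
                          stages$satellite_stage[usable],
                          config$threshold_range)
  stages$field_stage <- ifelse(is.na(stages$field_proportion), NA_character_,
                               classify_field_stage(stages$field_proportion,
                                                    scan$selected))
  em <- build_error_matrix(stages$field_stage[usable],
                           stages$satellite_stage[usable])
  structure(list(stages = stages,
                 cycles = rbind_all(cycles),
                 scan = scan$scan,
                 selected_threshold = scan$selected,
                 error_matrix = em,
                 metrics = accuracy_metrics(em),
                 excluded = rbind_all(excluded)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %d station-years staged, %d matched pairs\n",
              nrow(x$stages), x$metrics$total))
  cat(sprintf("selected threshold %d%% (overall accuracy %.1f%%)\n",
              x$selected_threshold, x$metrics$overall_accuracy))
  invisible(x)
}

#' Compare pheophytin proportions between high and low ice years
#'
#' Classifies every ice station-year as high/low ice under both schemes --
#' the breakup-date changepoint threshold (per station; stations with fewer
#' than four datable breakups fall back to the pooled all-station
#' changepoint) and the spring open-water concentration rule -- then compares
#' surface and depth-integrated pheophytin proportions between the ice bins
#' with Welch's t-test, one comparison per (level, scheme) cell. Cells with a
#' bin under two station-years are reported as not computable.
#'
#' @param pigments pigment sample table.
#' @param ice named list of [ice_series()].
#' @param config a [run_config()].
#' @return list of class `"ice_comparison_report"`: `ice_years` (per
#'   station-year breakup DOY, flags, threshold, and both class labels),
#'   `proportions` (per station-year surface and depth-integrated
#'   proportions joined with the classes), `comparison` (four-row summary
#'   table in the published layout).
#' @export
run_ice_comparison <- function(pigments, ice, config = run_config()) {
  if (length(ice) == 0L) stop_fmt("run_ice_comparison: no ice series supplied")
  br <- lapply(ice, breakup_doy, breakup_pct = config$breakup_pct,
               run_days = config$breakup_run_days)
  iy <- rbind_all(lapply(br, function(b)
    data.frame(station_id = b$station_id, year = b$year,
               breakup_doy = b$breakup_doy %||% NA_integer_,
               no_ice_flag = b$no_ice_flag)))
  iy$class_by_concentration <- vapply(
    ice, concentration_ice_class,
    run_days_exclusive = config$openwater_run_days_exclusive, "")
  iy <- iy[order(iy$station_id, iy$year), , drop = FALSE]

  pooled <- iy$breakup_doy[order(iy$year, iy$station_id)]
  pooled_thr <- if (sum(!is.na(pooled)) >= 4L)
    amoc_changepoint(pooled, penalty_factor = config$amoc_penalty_factor)$doy_threshold
  else NA_real_
  iy$doy_threshold <- NA_real_
  for (st in unique(iy$station_id)) {
    rows <- which(iy$station_id == st)
    bks <- iy$breakup_doy[rows]
    thr <- if (sum(!is.na(bks)) >= 4L)
      amoc_changepoint(bks, penalty_factor = config$amoc_penalty_factor)$doy_threshold
    else pooled_thr
    iy$doy_threshold[rows] <- thr
  }
  iy$class_by_breakup <- vapply(seq_len(nrow(iy)), function(i) {
    if (is.na(iy$doy_threshold[i])) return(NA_character_)
    b <- structure(list(station_id = iy$station_id[i], year = iy$year[i],
                        breakup_doy = iy$breakup_doy[i],
                        no_ice_flag = iy$no_ice_flag[i]),
                   class = "breakup_result")
    breakup_ice_class(b, iy$doy_threshold[i])
  }, "")

  pig_keys <- station_year_key(pigments$station_id, pigments$year)
  props <- rbind_all(lapply(unique(pig_keys), function(k) {
    sub <- pigments[pig_keys == k, , drop = FALSE]
    data.frame(station_id = sub$station_id[1], year = sub$year[1],
               surface = surface_proportion_of(sub, config$surface_depth_m),
               depth_integrated = tryCatch(profile_proportion_of(sub),
                                           error = function(e) NA_real_))
  }))
  props <- merge(props,
                 iy[, c("station_id", "year", "class_by_breakup",
                        "class_by_concentration")],
                 by = c("station_id", "year"), all.x = TRUE)

  cells <- expand.grid(level = c("surface", "depth_integrated"),
                       scheme = c("concentration", "breakup"),
                       stringsAsFactors = FALSE)
  comparison <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    vals <- props[[cells$level[i]]]
    cls <- props[[paste0("class_by_", cells$scheme[i])]]
    cbind(cells[i, , drop = FALSE],
          summarize_ice_groups(vals, cls, alpha = config$alpha))
  }))
  rownames(comparison) <- NULL
  structure(list(ice_years = iy, proportions = props, comparison = comparison),
            class = "ice_comparison_report")
}

#' @export
print.ice_comparison_report <- function(x, ...) {
  cat(sprintf("<ice_comparison_report> %d ice station-years, %d with pigments\n",
              nrow(x$ice_years), nrow(x$proportions)))
  print(x$comparison[, c("level", "scheme", "n_low", "n_high", "mean_low",
                         "mean_high", "t", "p", "significant")], digits = 3)
  invisible(x)
}

#' Write calibration results as CSV tables
#'
#' Writes `stages.csv`, `scan.csv`, `error_matrix.csv` (satellite classes as
#' columns), `cycles.csv`, and `excluded.csv` into `dir`.
#'
#' @param report a `"calibration_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_calibration_report <- function(report, dir) {
  stopifnot(inherits(report, "calibration_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_result_table(report$stages, file.path(dir, "stages.csv"))
  write_result_table(report$scan, file.path(dir, "scan.csv"))
  em <- report$error_matrix
  write_result_table(data.frame(field = rownames(em), EB = em[, "EB"],
                                PB = em[, "PB"]),
                     file.path(dir, "error_matrix.csv"))
  if (!is.null(report$cycles))
    write_result_table(report$cycles, file.path(dir, "cycles.csv"))
  if (!is.null(report$excluded))
    write_result_table(report$excluded, file.path(dir, "excluded.csv"))
  invisible(dir)
}

#' Write ice-comparison results as CSV tables
#'
#' Writes `ice_years.csv` and `comparison.csv` into `dir`.
#'
#' @param report an `"ice_comparison_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ice_comparison <- function(report, dir) {
  stopifnot(inherits(report, "ice_comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_result_table(report$ice_years, file.path(dir, "ice_years.csv"))
  write_result_table(report$comparison, file.path(dir, "comparison.csv"))
  invisible(dir)
}
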