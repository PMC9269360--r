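#' Pheophytin proportion of the combined pigment pool
#'
#' `pheo / (chl + pheo)`: the fraction of the chlorophyll-a + pheophytin pool
#' already degraded. Low while a bloom is growing, high once it matures.
#' Vectorized; units cancel (1 ug/L of pigment is numerically 1 mg/m3).
#'
#' @param chl chlorophyll-a concentration (>= 0).
#' @param pheo pheophytin concentration (>= 0).
#' @return proportion(s) in \[0, 1\].
#' @export
#' @examples
#' pheophytin_proportion(7.2, 2.8) # 0.28
pheophytin_proportion <- function(chl, pheo) {
  stopifnot(length(chl) == length(pheo))
  if (anyNA(chl) || anyNA(pheo) || any(chl < 0) || any(pheo < 0))
    stop_fmt("pheophytin_proportion: concentrations must be non-negative")
  tot <- chl + pheo
  if (any(tot == 0))
    stop_fmt("pheophytin_proportion: undefined when chl + pheo = 0 (below detection)")
  pheo / tot
}

#' Classify a field sample as Early or Post Bloom by threshold
#'
#' Early Bloom when the pheophytin proportion is strictly below
#' `threshold_pct` percent; proportions at or above the threshold are Post
#' Bloom (equality goes to PB so that EB stays strictly pre-peak).
#'
#' @param p pheophytin proportion(s) in \[0, 1\].
#' @param threshold_pct integer percentage threshold in \[0, 100\].
#' @return character vector of `"EB"` / `"PB"`.
#' @export
classify_field_stage <- function(p, threshold_pct) {
  stopifnot(length(threshold_pct) == 1L, threshold_pct >= 0, threshold_pct <= 100,
            threshold_pct == round(threshold_pct))
  ifelse(p < threshold_pct / 100, "EB", "PB")
}

#' Field-vs-satellite error matrix
#'
#' Tabulates paired field and satellite EB/PB labels with the satellite
#' classes as the reference columns and the field classes as rows, mirroring
#' the orientation used for land-cover accuracy assessment.
#'
#' @param field_labels,satellite_labels equal-length character vectors of
#'   `"EB"` / `"PB"` for station-years having both labels.
#' @return 2x2 integer matrix of class `"error_matrix"` (rows = field,
#'   columns = satellite).
#' @export
build_error_matrix <- function(field_labels, satellite_labels) {
  if (length(field_labels) == 0L || length(satellite_labels) == 0L)
    stop_fmt("build_error_matrix: empty label lists")
  if (length(field_labels) != length(satellite_labels))
    stop_fmt("build_error_matrix: label lists differ in length (%d vs %d)",
             length(field_labels), length(satellite_labels))
  lv <- c("EB", "PB")
  if (!all(field_labels %in% lv) || !all(satellite_labels %in% lv))
    stop_fmt("build_error_matrix: labels must be 'EB' or 'PB'")
  m <- table(factor(field_labels, lv), factor(satellite_labels, lv))
  m <- matrix(as.integer(m), 2L, 2L,
              dimnames = list(field = lv, satellite = lv))
  class(m) <- c("error_matrix", class(m))
  m
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("Field vs satellite error matrix (columns = satellite reference):\n")
  print(unclass(x))
  met <- accuracy_metrics(x)
  cat(sprintf("overall accuracy %.1f%% (%d consistent / %d inconsistent)\n",
              met$overall_accuracy, met$consistent, met$inconsistent))
  invisible(x)
}

#' Accuracy metrics of an error matrix
#'
#' Overall accuracy is the percent of agreeing pairs. Per satellite
#' (reference) class, producer's accuracy is the percent of that class's
#' reference column recovered and omission its complement; per field
#' (predicted) class, user's accuracy is the percent of that class's row that
#' is correct and commission its complement. A class with an empty column or
#' row reports `NA` for its metric; the others are still computed.
#'
#' @param m an `"error_matrix"`.
#' @return list with `overall_accuracy`, `consistent`, `inconsistent`,
#'   `total`, and named (`EB`, `PB`) vectors `producer_accuracy`, `omission`,
#'   `user_accuracy`, `commission`, all in percent.
#' @export
accuracy_metrics <- function(m) {
  stopifnot(inherits(m, "error_matrix"))
  total <- sum(m)
  if (total == 0L) stop_fmt("accuracy_metrics: empty matrix")
  consistent <- m[1, 1] + m[2, 2]
  colt <- colSums(m); rowt <- rowSums(m)
  producer <- ifelse(colt > 0, 100 * diag(m) / colt, NA_real_)
  user <- ifelse(rowt > 0, 100 * diag(m) / rowt, NA_real_)
  names(producer) <- names(user) <- c("EB", "PB")
  list(overall_accuracy = 100 * consistent / total,
       consistent = as.integer(consistent),
       inconsistent = as.integer(total - consistent),
       total = as.integer(total),
       producer_accuracy = producer,
       omission = 100 - producer,
       user_accuracy = user,
       commission = 100 - user)
}

#' Scan integer thresholds against satellite stages
#'
#' Classifies the matched proportions at every integer percentage threshold in
#' `threshold_range`, scores each with [accuracy_metrics()], and selects the
#' threshold maximizing overall accuracy. Ties break lexicographically: first
#' toward balanced omission between the classes (smallest
#' `|omission(EB) - omission(PB)|`, an undefined omission counting as
#' unbalanced), then toward the smallest threshold.
#'
#' @param proportions pheophytin proportions of the matched station-years.
#' @param satellite_labels their satellite stages (`"EB"` / `"PB"`).
#' @param threshold_range inclusive integer pair, default `c(0L, 100L)`.
#' @return list of class `"threshold_scan"`: `scan` (one row per threshold
#'   with accuracy, omission, and commission columns) and `selected`.
#' @export
scan_thresholds <- function(proportions, satellite_labels,
                            threshold_range = c(0L, 100L)) {
  if (length(proportions) == 0L)
    stop_fmt("scan_thresholds: no matched proportion/satellite pairs")
  if (length(proportions) != length(satellite_labels))
    stop_fmt("scan_thresholds: inputs differ in length")
  ts <- seq(threshold_range[1], threshold_range[2])
  rows <- lapply(ts, function(tt) {
    met <- accuracy_metrics(
      build_error_matrix(classify_field_stage(proportions, tt), satellite_labels))
    data.frame(threshold_pct = tt,
               overall_accuracy = met$overall_accuracy,
               omission_EB = met$omission[["EB"]],
               commission_EB = met$commission[["EB"]],
               omission_PB = met$omission[["PB"]],
               commission_PB = met$commission[["PB"]])
  })
  scan <- do.call(rbind, rows)
  bias <- abs(scan$omission_EB - scan$omission_PB)
  bias[is.na(bias)] <- Inf
  sel <- order(-scan$overall_accuracy, bias, scan$threshold_pct)[1]
  structure(list(scan = scan, selected = scan$threshold_pct[sel]),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  best <- x$scan[x$scan$threshold_pct == x$selected, ]
  cat(sprintf("<threshold_scan> %d thresholds; selected %d%% (overall accuracy %.1f%%)\n",
              nrow(x$scan), x$selected, best$overall_accuracy))
  invisible(x)
}
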