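#' Depth-integrated pheophytin proportion of one profile
#'
#' Chlorophyll-a and pheophytin are integrated separately over the sampled
#' depths by the trapezoidal rule (no extrapolation to the surface or
#' seafloor), and the proportion is the ratio of the integrals -- the
#' pigment-mass interpretation of a depth-integrated proportion. A
#' single-depth profile degenerates to the pointwise proportion.
#'
#' @param depth_m sample depths (m, positive downward, distinct).
#' @param chl,pheo concentrations (ug/L) at each depth.
#' @return list: `int_chl`, `int_pheo` (mg/m2), `proportion`.
#' @export
#' @examples
#' depth_integrated_proportion(c(5, 25), chl = c(2, 0), pheo = c(0, 2))$proportion # 0.5
depth_integrated_proportion <- function(depth_m, chl, pheo) {
  stopifnot(length(depth_m) >= 1L,
            length(chl) == length(depth_m), length(pheo) == length(depth_m))
  if (anyDuplicated(depth_m))
    stop_fmt("depth_integrated_proportion: depths must be distinct")
  if (any(depth_m <= 0) || any(chl < 0) || any(pheo < 0))
    stop_fmt("depth_integrated_proportion: depths must be > 0 and pigments >= 0")
  o <- order(depth_m)
  d <- depth_m[o]
  if (length(d) == 1L) {
    ic <- chl; ip <- pheo
  } else {
    # ug/L over metres integrates to mg/m2 (1 ug/L = 1 mg/m3)
    ic <- pracma::trapz(d, chl[o])
    ip <- pracma::trapz(d, pheo[o])
  }
  if (ic + ip == 0)
    stop_fmt("depth_integrated_proportion: both pigment integrals are zero")
  list(int_chl = as.numeric(ic), int_pheo = as.numeric(ip),
       proportion = as.numeric(ip / (ic + ip)))
}

welch_record <- function(n1, m1, s1, n2, m2, s2, t, df, p, alpha) {
  list(t = t, df = df, p = p, significant = p < alpha,
       groups = data.frame(group = c("a", "b"), n = c(n1, n2),
                           mean = c(m1, m2), sd = c(s1, s2)))
}

#' Welch's unequal-variance t-test on raw samples
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = FALSE`, returning the
#' statistic, Welch-Satterthwaite degrees of freedom, and two-sided p-value.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param alpha significance level used for the `significant` flag.
#' @return list: `t`, `df`, `p`, `significant`, `groups` (per-group n, mean, sd).
#' @export
welch_t <- function(a, b, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop_fmt("welch_t: each group needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop_fmt("welch_t: both groups have zero variance")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  welch_record(length(a), mean(a), stats::sd(a),
               length(b), mean(b), stats::sd(b),
               unname(ht$statistic), unname(ht$parameter), ht$p.value, alpha)
}

#' Welch's t-test from summary statistics
#'
#' Direct evaluation of the Welch statistic and Welch-Satterthwaite degrees
#' of freedom from group sizes, means, and standard deviations -- the route
#' for checking published summary tables when raw values are unavailable.
#'
#' @param n1,m1,s1 size, mean, sd of group 1.
#' @param n2,m2,s2 size, mean, sd of group 2.
#' @param alpha significance level used for the `significant` flag.
#' @return list as in [welch_t()].
#' @export
#' @examples
#' welch_t_from_summary(20, 0.25, 0.07, 51, 0.34, 0.15)$t # about -3.44
welch_t_from_summary <- function(n1, m1, s1, n2, m2, s2, alpha = 0.05) {
  if (n1 < 2L || n2 < 2L)
    stop_fmt("welch_t_from_summary: each group needs n >= 2")
  if (s1 < 0 || s2 < 0) stop_fmt("welch_t_from_summary: sd must be >= 0")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  if (v1 + v2 == 0) stop_fmt("welch_t_from_summary: both groups have zero variance")
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  welch_record(n1, m1, s1, n2, m2, s2, t, df, p, alpha)
}

#' Compare pheophytin proportions between low and high ice years
#'
#' Summarizes each ice-year bin (n, mean, SD, min, max of the station-year
#' proportions) and tests the difference in means with Welch's t-test. A bin
#' with fewer than two station-years makes the comparison not computable; the
#' summaries that exist are still reported.
#'
#' @param proportions station-year pheophytin proportions.
#' @param ice_class matching `"LOW"` / `"HIGH"` labels.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: `n_low`, `mean_low`, `sd_low`, `min_low`,
#'   `max_low`, the same for `high`, then `t`, `df`, `p`, `significant`,
#'   `computable`.
#' @export
summarize_ice_groups <- function(proportions, ice_class, alpha = 0.05) {
  stopifnot(length(proportions) == length(ice_class))
  keep <- !is.na(proportions) & ice_class %in% c("LOW", "HIGH")
  p <- proportions[keep]; cls <- ice_class[keep]
  summ <- function(v) {
    if (length(v) == 0L) c(n = 0L, mean = NA, sd = NA, min = NA, max = NA)
    else c(n = length(v), mean = mean(v),
           sd = if (length(v) > 1L) stats::sd(v) else NA,
           min = min(v), max = max(v))
  }
  lo <- summ(p[cls == "LOW"]); hi <- summ(p[cls == "HIGH"])
  out <- data.frame(n_low = as.integer(lo["n"]), mean_low = lo["mean"],
                    sd_low = lo["sd"], min_low = lo["min"], max_low = lo["max"],
                    n_high = as.integer(hi["n"]), mean_high = hi["mean"],
                    sd_high = hi["sd"], min_high = hi["min"], max_high = hi["max"],
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    significant = NA, computable = FALSE,
                    row.names = NULL)
  if (lo["n"] >= 2 && hi["n"] >= 2 &&
      (stats::var(p[cls == "LOW"]) > 0 || stats::var(p[cls == "HIGH"]) > 0)) {
    wt <- welch_t(p[cls == "LOW"], p[cls == "HIGH"], alpha = alpha)
    out$t <- wt$t; out$df <- wt$df; out$p <- wt$p
    out$significant <- wt$significant; out$computable <- TRUE
  }
  out
}
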