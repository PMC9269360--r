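make_series <- function(doy, chl, station = "ST1", year = 2015L) {
  chl_series(station, year, doy, chl)
}

test_that("ice masking removes days strictly above the threshold", {
  s <- make_series(c(90, 100, 110), c(0.5, 0.6, 0.7))
  ice40 <- ice_series("ST1", 2015, c(90, 100, 110), c(0, 40, 0))
  m <- mask_ice_days(s, ice40)
  expect_equal(m$observations$doy, c(90L, 110L))
  expect_equal(m$masked_doys, 100L)

  ice15 <- ice_series("ST1", 2015, c(90, 100, 110), c(0, 15, 0))
  expect_equal(nrow(mask_ice_days(s, ice15)$observations), 3L) # boundary retained

  ice0 <- ice_series("ST1", 2015, 1:365, rep(0, 365))
  expect_equal(mask_ice_days(s, ice0)$observations, s$observations)

  # missing ice data retains the observation
  ice_gap <- ice_series("ST1", 2015, c(90, 110), c(0, 0))
  expect_equal(nrow(mask_ice_days(s, ice_gap)$observations), 3L)

  other <- ice_series("ST2", 2015, 1:10, rep(0, 10))
  expect_error(mask_ice_days(s, other), "ST2")
})

test_that("quality control fails on count, gap, and window rules", {
  cfg <- run_config()
  few <- make_series(seq(150, 230, by = 20), rep(0.5, 5))
  expect_false(qc_series(few, cfg)$pass)
  expect_equal(qc_series(few, cfg)$rule, "min_observations")

  doys <- c(seq(120, 178, by = 2), seq(208, 230, by = 12)) # 30-day hole
  gap <- make_series(doys, rep(0.5, length(doys)))
  expect_equal(qc_series(gap, cfg)$rule, "max_gap")

  even <- make_series(seq(160, 236, by = 4), rep(0.5, 20))
  expect_true(qc_series(even, cfg)$pass)
  expect_true(sum(even$observations$doy >= 174 & even$observations$doy <= 219) >= 3)

  # enough observations, but only 2 inside DOY 174-219
  sparse_win <- make_series(c(seq(150, 172, by = 4), 190, 210, 228, 240),
                            rep(0.5, 10))
  expect_equal(qc_series(sparse_win, cfg)$rule, "window_min_obs")

  # a series ending 25+ days before the window closes trips the gap rule
  early_end <- make_series(seq(150, 190, by = 5), rep(0.5, 9))
  expect_equal(qc_series(early_end, cfg)$rule, "max_gap")

  # masking can push a passing series into failure
  ice <- ice_series("ST1", 2015, 1:365, ifelse(1:365 %in% 180:206, 80, 0))
  masked <- mask_ice_days(make_series(seq(160, 236, by = 4), rep(0.5, 20)), ice)
  expect_false(qc_series(masked, cfg)$pass)
})

test_that("smoothing preserves constants and linear trends exactly", {
  doys <- seq(140, 240, by = 5)
  const <- fit_phenology_curve(make_series(doys, rep(0.3, length(doys))))
  expect_equal(const$chl, rep(0.3, length(const$doy)), tolerance = 1e-10)
  expect_equal(const$doy, 140:240)

  lin <- fit_phenology_curve(make_series(doys, 0.1 + 0.02 * doys))
  expect_equal(lin$chl, 0.1 + 0.02 * (140:240), tolerance = 1e-8)

  expect_error(fit_phenology_curve(make_series(doys, rep(0.3, 21)), span = 2),
               "span")
  # never extrapolates beyond the observed DOY range
  expect_equal(range(lin$doy), c(140L, 240L))
})

# bloom 140/150/160 between strict local minima, NB shoulders on both sides
shouldered_pulse <- function(top = 1.0) {
  daily_curve(130:170, c(seq(0.4, 0.2, length.out = 11),
                         seq(0.2, top, length.out = 11)[-1],
                         seq(top, 0.2, length.out = 11)[-1],
                         seq(0.2, 0.3, length.out = 11)[-1]))
}

test_that("bloom cycle detection applies the rise threshold and boundaries", {
  flat <- daily_curve(100:200, rep(0.3, 101))
  expect_equal(nrow(detect_bloom_cycles(flat)), 0L)

  cyc <- detect_bloom_cycles(shouldered_pulse())
  expect_equal(nrow(cyc), 1L)
  expect_equal(c(cyc$t1, cyc$t2, cyc$t3), c(140, 150, 160))
  expect_equal(cyc$amplitude, 0.8)
  expect_false(cyc$truncated_end)

  # a pure triangle spanning the whole grid uses the grid ends as bounds
  tri <- daily_curve(140:160, c(seq(0.2, 1.0, length.out = 11),
                                seq(1.0, 0.2, length.out = 11)[-1]))
  cyc_tri <- detect_bloom_cycles(tri)
  expect_equal(c(cyc_tri$t1, cyc_tri$t2, cyc_tri$t3), c(140, 150, 160))

  expect_equal(nrow(detect_bloom_cycles(shouldered_pulse(top = 0.6))), 0L) # rise 0.4

  two <- daily_curve(100:220, 0.2 + 1.5 * exp(-0.5 * ((100:220 - 140) / 8)^2) +
                       1.0 * exp(-0.5 * ((100:220 - 190) / 8)^2))
  cyc2 <- detect_bloom_cycles(two)
  expect_equal(nrow(cyc2), 2L)
  expect_true(cyc2$t3[1] <= cyc2$t1[2])
  expect_equal(cyc2$t2, c(140, 190))
})

test_that("peak plateaus resolve to their earliest day", {
  v <- c(rep(0.2, 5), seq(0.2, 1, length.out = 6)[-1], rep(1, 4),
         seq(1, 0.2, length.out = 6)[-1], rep(0.2, 5))
  cyc <- detect_bloom_cycles(daily_curve(100 + seq_along(v) - 1, v))
  expect_equal(nrow(cyc), 1L)
  expect_equal(cyc$t2, 100 + 9) # first day of the maximal plateau
})

test_that("sub-threshold continuations merge only above the bloom baseline", {
  # shoulder bump whose shared minimum (0.5) stays above the bloom start (0.2)
  v1 <- c(0.2, 0.6, 1.0, 0.8, 0.5, 0.7, 0.8, 0.6, 0.4, 0.3)
  c1 <- detect_bloom_cycles(daily_curve(140:149, v1))
  expect_equal(nrow(c1), 1L)
  expect_equal(c(c1$t1, c1$t2, c1$t3), c(140, 142, 149))

  # bump separated by a return to the baseline: minor variability, no merge
  v2 <- c(0.2, 0.6, 1.0, 0.6, 0.2, 0.4, 0.5, 0.4, 0.3, 0.2)
  c2 <- detect_bloom_cycles(daily_curve(140:149, v2))
  expect_equal(nrow(c2), 1L)
  expect_equal(c(c2$t1, c2$t2, c2$t3), c(140, 142, 144))
})

test_that("a bloom cut off by the series end is flagged truncated", {
  rising <- daily_curve(150:190, 0.2 + 0.02 * (0:40))
  cyc <- detect_bloom_cycles(rising)
  expect_equal(nrow(cyc), 1L)
  expect_true(cyc$truncated_end)
  expect_equal(cyc$t3, 190)
})

test_that("cycle detection matches the brute-force oracle on short curves", {
  for (seed in 1:150) {
    cv <- random_daily_curve(sample(10:60, 1), seed)
    got <- detect_bloom_cycles(cv)
    want <- oracle_cycles(cv$doy, cv$chl)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$t1, want$t1, info = paste("seed", seed))
      expect_equal(got$t2, want$t2, info = paste("seed", seed))
      expect_equal(got$t3, want$t3, info = paste("seed", seed))
    }
  }
})

test_that("detected cycles are ordered, disjoint, and above the rise threshold", {
  for (seed in 151:230) {
    cv <- random_daily_curve(sample(20:80, 1), seed)
    cyc <- detect_bloom_cycles(cv)
    if (nrow(cyc) == 0L) next
    expect_true(all(cyc$t1 < cyc$t2))
    expect_true(all(cyc$t2 <= cyc$t3))
    expect_true(all(cyc$amplitude >= 0.5))
    expect_true(all(diff(cyc$t1) > 0))
    if (nrow(cyc) > 1L) expect_true(all(cyc$t3[-nrow(cyc)] <= cyc$t1[-1]))
    # peak value is the curve maximum over the cycle
    for (i in seq_len(nrow(cyc))) {
      seg <- cv$chl[which(cv$doy == cyc$t1[i]):which(cv$doy == cyc$t3[i])]
      expect_equal(cyc$chl_t2[i], max(seg))
    }
  }
})

test_that("stage classification follows the cycle boundaries", {
  cyc <- detect_bloom_cycles(shouldered_pulse()) # cycle (140, 150, 160)
  expect_equal(classify_stage(cyc, 135), "NB") # before the bloom starts
  expect_equal(classify_stage(cyc, 140), "EB")
  expect_equal(classify_stage(cyc, 150), "EB")
  expect_equal(classify_stage(cyc, 151), "PB")
  expect_equal(classify_stage(cyc, 160), "PB")
  expect_equal(classify_stage(cyc, 161), "NB")
  expect_error(classify_stage(cyc, 120), "coverage")

  none <- detect_bloom_cycles(daily_curve(100:200, rep(0.3, 101)))
  expect_equal(classify_stage(none, 150), "NB")
})

test_that("every grid day receives exactly one stage", {
  for (seed in 301:320) {
    cv <- random_daily_curve(sample(20:70, 1), seed)
    cyc <- detect_bloom_cycles(cv)
    stages <- vapply(cv$doy, function(d) classify_stage(cyc, d), "")
    expect_true(all(stages %in% c("NB", "EB", "PB")))
  }
})

test_that("a noiseless single-pulse series yields the generating peak exactly", {
  for (peak in c(150, 175, 196)) {
    spec <- bloom_spec(pulses = list(c(peak, 2, 8)), noise_cv = 0,
                       cloud_prob = 0, seed = 1)
    g <- gen_chl_series(spec)
    curve <- fit_phenology_curve(g$series)
    cyc <- detect_bloom_cycles(curve)
    expect_equal(nrow(cyc), 1L)
    expect_equal(cyc$t2, peak)
  }
})
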