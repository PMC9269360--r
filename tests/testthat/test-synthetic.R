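test_that("generators are deterministic under a fixed seed", {
  a <- gen_chl_series(bloom_spec(seed = 31))
  b <- gen_chl_series(bloom_spec(seed = 31))
  expect_identical(a$series$observations, b$series$observations)

  d1 <- gen_calibration_dataset(20, seed = 8)
  d2 <- gen_calibration_dataset(20, seed = 8)
  expect_identical(d1$pairs, d2$pairs)
  expect_identical(d1$samples, d2$samples)

  f1 <- gen_full_study(seed = 3, stations = c("A", "B"), years = 2013:2016)
  f2 <- gen_full_study(seed = 3, stations = c("A", "B"), years = 2013:2016)
  expect_identical(f1$pigments, f2$pigments)
  expect_identical(f1$ice[[1]]$conc, f2$ice[[1]]$conc)
})

test_that("generated series satisfy their consumers' invariants", {
  for (seed in 1:10) {
    g <- gen_chl_series(bloom_spec(seed = seed))
    obs <- g$series$observations
    expect_true(all(diff(obs$doy) > 0))
    expect_true(all(obs$chl >= 0))
    s <- gen_ice_series(ice_spec(breakup_doy_true = 100 + 5 * seed))
    expect_true(all(s$conc[s$coverage] >= 0 & s$conc[s$coverage] <= 100))
  }
})

test_that("cloud thinning yields the intended observation density", {
  spec <- bloom_spec(cloud_prob = 0.93, obs_window = c(1L, 365L), seed = 123)
  counts <- numeric(50)
  set.seed(123)
  for (i in 1:50) {
    keep <- runif(365) > 0.93
    counts[i] <- sum(keep)
  }
  # binomial expectation 365 * 0.07 = 25.6 observations per year
  expect_lt(abs(mean(counts) - 25.55), 2.5)
  g <- gen_chl_series(spec)
  expect_lt(abs(nrow(g$series$observations) - 25.55), 16) # a single draw
})

test_that("generating truth records the constructed bloom cycles", {
  spec <- bloom_spec(pulses = list(c(150, 2, 8), c(210, 1.2, 7)),
                     noise_cv = 0, cloud_prob = 0, seed = 1)
  g <- gen_chl_series(spec)
  expect_equal(nrow(g$truth$cycles), 2L)
  expect_equal(g$truth$cycles$t2, c(150, 210))
})

test_that("synthetic ice reproduces its breakup day and episode classes", {
  for (bk in c(100L, 120L, 150L)) {
    s <- gen_ice_series(ice_spec(breakup_doy_true = bk))
    expect_equal(breakup_doy(s)$breakup_doy, bk)
  }
  # a breakup after the spring window keeps the year HIGH by concentration;
  # a DOY-100 breakup melts out inside March-May and flags LOW on its own
  expect_equal(concentration_ice_class(gen_ice_series(ice_spec(breakup_doy_true = 150L))),
               "HIGH")
  expect_equal(concentration_ice_class(gen_ice_series(ice_spec(breakup_doy_true = 100L))),
               "LOW")
  lowice <- gen_ice_series(ice_spec(breakup_doy_true = 120,
                                    openwater_episodes = list(c(70, 11))))
  expect_equal(concentration_ice_class(lowice), "LOW")

  expect_error(gen_ice_series(ice_spec(breakup_doy_true = 100,
                                       openwater_episodes = list(c(80, 20)))),
               "overlaps")
})

test_that("pigment profiles follow the stage regimes and deepen in proportion", {
  set.seed(17)
  for (i in 1:10) {
    eb <- gen_pigment_samples(pigment_spec(), "EB")
    pb <- gen_pigment_samples(pigment_spec(), "PB")
    p_eb <- pheophytin_proportion(eb$chl_ug_L, eb$pheo_ug_L)
    p_pb <- pheophytin_proportion(pb$chl_ug_L, pb$pheo_ug_L)
    expect_lt(p_eb[1], 0.28)
    expect_gte(p_pb[1], 0.28)
    expect_equal(nrow(eb), 5L)
    expect_true(all(p_eb >= p_eb[1] - 1e-12)) # depth never dips below the surface
  }
  # and the mean profile deepens: pheopigment accumulates with depth
  profs <- replicate(200, {
    s <- gen_pigment_samples(pigment_spec(), "EB")
    pheophytin_proportion(s$chl_ug_L, s$pheo_ug_L)
  })
  expect_true(all(diff(rowMeans(profs)) > 0))
})

test_that("anchored calibration sets are solved exactly at the boundary", {
  for (seed in c(2, 9, 57)) {
    d <- gen_calibration_dataset(28, seed = seed)
    sc <- scan_thresholds(d$pairs$proportion, d$pairs$satellite_stage)
    expect_equal(sc$selected, 28L)
  }
  small <- gen_calibration_dataset(4, seed = 1)
  expect_equal(nrow(small$pairs), 4L)
  expect_setequal(unique(small$pairs$satellite_stage), c("EB", "PB"))
  sc <- scan_thresholds(small$pairs$proportion, small$pairs$satellite_stage)
  expect_true(sc$selected >= 0 && sc$selected <= 100)
})

test_that("the matched-table replica reproduces the published matrix cells", {
  t1 <- table1_dataset()
  em <- build_error_matrix(classify_field_stage(t1$pairs$proportion, 28),
                           t1$pairs$satellite_stage)
  expect_equal(as.vector(unclass(em)), c(16L, 7L, 0L, 5L))
  # the seven satellite-EB misclassifications span the reported 29-61% range
  mis <- t1$pairs$proportion[t1$pairs$satellite_stage == "EB" &
                               t1$pairs$proportion >= 0.28]
  expect_equal(length(mis), 7L)
  expect_equal(range(mis), c(0.29, 0.61))
})

test_that("the full-study generator matches the observing design", {
  fs <- gen_full_study(seed = 4)
  expect_length(fs$chl, 13 * 7)
  expect_length(fs$ice, 13 * 7)
  expect_equal(nrow(fs$meta), 91L)
  # winter ice never forms at two stations in the anomalous year
  noice <- vapply(fs$ice[c("SLIP-1:2018", "SLIP-2:2018")],
                  function(s) breakup_doy(s)$no_ice_flag, TRUE)
  expect_true(all(noice))
  # low-ice regime years are flagged LOW by the concentration rule
  cls <- vapply(fs$ice, concentration_ice_class, "")
  keys <- paste(fs$meta$station_id, fs$meta$year, sep = ":")
  expect_true(all(cls[keys][fs$meta$regime == "LOW"] == "LOW"))
  expect_true(all(cls[keys][fs$meta$regime == "HIGH"] == "HIGH"))
})
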