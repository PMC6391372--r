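test_that("saturation vapor pressure matches the printed constant and oracle", {
  expect_equal(saturation_vapor_pressure(0), 0.6107)
  grid <- seq(-30, 45, length.out = 40)
  expect_equal(saturation_vapor_pressure(grid), es_oracle(grid), tolerance = 1e-12)
  # strictly increasing
  expect_true(all(diff(saturation_vapor_pressure(seq(-50, 50, by = 0.5))) > 0))
  expect_error(saturation_vapor_pressure(NaN), "finite")
  expect_error(saturation_vapor_pressure(80), "range")
})

test_that("daily Vpd is es(tmax) - es(tmin), non-negative, monotone in tmax", {
  expect_equal(daily_vpd(15, 15), 0)
  expect_equal(daily_vpd(30, 18), es_oracle(30) - es_oracle(18))
  tmaxes <- seq(18, 40, by = 0.5)
  expect_true(all(diff(daily_vpd(tmaxes, rep(18, length(tmaxes)))) > 0))
  expect_error(daily_vpd(10, 12), "tmax < tmin")
})

test_that("relative humidity follows the half-sum definition", {
  tmax <- 25; tmin <- 12
  half <- (es_oracle(tmax) + es_oracle(tmin)) / 2
  expect_equal(daily_relative_humidity(half, tmax, tmin), 1.0)
  expect_equal(daily_relative_humidity(0, tmax, tmin), 0)
  expect_equal(daily_relative_humidity(1.2, tmax, tmin), 1.2 / half)
  expect_message(daily_relative_humidity(5, tmax, tmin), "exceed 1")
  expect_error(daily_relative_humidity(-0.1, tmax, tmin), "non-negative")
})

test_that("window bins are half-open 30-day intervals anchored on sowing", {
  expect_equal(window_of(-30), "Wpre")
  expect_equal(window_of(-1), "Wpre")
  expect_equal(window_of(0), "W1")
  expect_equal(window_of(29), "W1")
  expect_equal(window_of(30), "W2")
  expect_equal(window_of(c(60, 90, 120, 149)), c("W3", "W4", "W5", "W5"))
  expect_true(is.na(window_of(150)))
  expect_true(is.na(window_of(-31)))
})

test_that("tree predictor set has exactly 31 members", {
  tp <- tree_predictor_names()
  expect_length(tp, 31)
  expect_true("state" %in% tp)
  expect_false(any(grepl("tmin|dayl", tp)))
  expect_false(any(grepl("tmin|dayl", boost_predictor_names())))
})

test_that("constant weather gives closed-form window features", {
  w <- constant_weather(tmax = 25, tmin = 15, precip = 2)
  f <- aggregate_windows(w, sowing_doy = 150)
  for (lab in window_labels()) {
    expect_equal(f[[paste0("precip_cum_", lab)]], 60)
    expect_equal(f[[paste0("wet_days_", lab)]], 30)
    expect_equal(f[[paste0("dry_days_", lab)]], 0)
    expect_equal(f[[paste0("ab_ratio_flag_", lab)]], 1)
    expect_equal(f[[paste0("vpd_mean_", lab)]], es_oracle(25) - es_oracle(15))
  }
  expect_equal(f$precip_cum_season, 360)
})

test_that("zero precipitation yields 30 dry days and a flagged zero ratio", {
  w <- constant_weather(precip = 0)
  f <- aggregate_windows(w, sowing_doy = 120)
  expect_equal(f$wet_days_W2, 0)
  expect_equal(f$dry_days_W2, 30)
  expect_equal(f$ab_ratio_W2, 0)
  expect_equal(f$ab_ratio_flag_W2, 0)  # flag marks dry_days == 0, not wet == 0
})

test_that("precipitation of exactly 1 mm counts as neither wet nor dry", {
  w <- constant_weather(precip = 1)
  f <- aggregate_windows(w, sowing_doy = 120)
  expect_equal(f$wet_days_W1, 0)
  expect_equal(f$dry_days_W1, 0)
  expect_equal(f$ab_ratio_flag_W1, 1)
})

test_that("vectorized aggregation equals the brute-force day loop", {
  for (s in 1:25) {
    w <- random_weather_year(seed = s)
    sow <- sample(80:180, 1)
    f <- aggregate_windows(w, sowing_doy = sow)
    o <- window_oracle(w, sow)
    expect_equal(unlist(f[1, names(o)]), o, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("permuting days within a window leaves its features unchanged", {
  w <- random_weather_year(seed = 7)
  sow <- 130
  f0 <- aggregate_windows(w, sow)
  # shuffle the W3 days (offsets 60..89) among themselves
  idx <- which(w$doy %in% (sow + 60):(sow + 89))
  set.seed(1)
  perm <- sample(idx)
  w2 <- w
  w2[idx, c("tmin", "tmax", "precip", "srad", "vp", "dayl")] <-
    w[perm, c("tmin", "tmax", "precip", "srad", "vp", "dayl")]
  f1 <- aggregate_windows(w2, sow)
  expect_equal(f1, f0, tolerance = 1e-12)
})

test_that("coverage gaps are rejected with the missing offsets listed", {
  w <- random_weather_year(seed = 3)
  w <- w[w$doy != 150, ]
  expect_error(aggregate_windows(w, sowing_doy = 140), "offsets")
})

test_that("windows may span a year boundary", {
  w1 <- random_weather_year(seed = 11, year = 2009L)
  w2 <- random_weather_year(seed = 12, year = 2010L)
  w <- rbind(w1, w2)
  f <- aggregate_windows(w, sowing_doy = 20, sowing_year = 2010L)
  # Wpre (offsets -30..-1) covers doys 355..365 of 2009 plus 1..19 of 2010
  expected <- sum(w1$precip[w1$doy %in% 355:365]) +
    sum(w2$precip[w2$doy %in% 1:19])
  expect_equal(f$precip_cum_Wpre, expected, tolerance = 1e-10)
})
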