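test_that("a zero shift reproduces the unshifted features exactly", {
  w <- random_weather_year(seed = 21)
  f0 <- aggregate_windows(w, 130)
  fs <- shift_features(w, 130, 0)
  expect_identical(f0, fs)
})

test_that("shifting is equivalent to translating the sowing date", {
  w <- random_weather_year(seed = 22)
  expect_equal(shift_features(w, 120, 10), aggregate_windows(w, 130))
  expect_equal(shift_features(w, 140, -15), aggregate_windows(w, 125))
})

test_that("constant weather makes features shift-invariant", {
  w <- constant_weather()
  f <- lapply(c(-30, 0, 30), function(s) shift_features(w, 150, s))
  expect_equal(f[[1]], f[[2]])
  expect_equal(f[[2]], f[[3]])
})

test_that("the scenario grid has exactly state-years x shifts rows", {
  cc <- small_study()
  dat <- cc$dat
  trials <- dat$trials
  sy <- aggregate_state_year(trials, dat$features,
                             coords = data.frame(state = cc$cfg$states$state,
                                                 latitude = cc$cfg$states$latitude,
                                                 longitude = cc$cfg$states$longitude))
  offset_model <- fit_boost(sy[, boost_predictor_names()], sy$yield,
                            boost_controls(n_iter = 0))
  scen <- run_scenarios(sy, trials, dat$weather, offset_model)
  expect_equal(nrow(scen), nrow(sy) * 7)
  expect_true(all(table(paste(scen$state, scen$year)) == 7))
  expect_true(all(scen$shift_days %in% seq(-30, 30, 10)))
  expect_true(0 %in% scen$shift_days)
  # constant-offset model: every prediction identical
  expect_equal(length(unique(scen$pred_yield_kg_ha)), 1)
})

test_that("scenario failures are collected row-wise and the run continues", {
  cc <- small_study()
  dat <- cc$dat
  trials <- dat$trials
  sy <- aggregate_state_year(trials, dat$features,
                             coords = data.frame(state = cc$cfg$states$state,
                                                 latitude = cc$cfg$states$latitude,
                                                 longitude = cc$cfg$states$longitude))
  offset_model <- fit_boost(sy[, boost_predictor_names()], sy$yield,
                            boost_controls(n_iter = 0))
  # truncate one location's weather so its -30 shift cannot be built
  loc1 <- trials$location_id[1]
  w2 <- dat$weather
  drop <- w2$location_id == loc1 & w2$year == min(w2$year) & w2$doy < 75
  w2 <- w2[!drop, ]
  expect_message(scen <- run_scenarios(sy, trials, w2, offset_model),
                 "failed")
  expect_equal(nrow(scen), nrow(sy) * 7)
  expect_true(any(is.na(scen$pred_yield_kg_ha)))
  expect_gt(length(attr(scen, "failures")), 0)
  # unaffected scenarios still predicted
  expect_true(sum(!is.na(scen$pred_yield_kg_ha)) > nrow(sy) * 5)
})

test_that("mean W3 Vpd is flat-to-increasing with delayed sowing", {
  # the generator places the seasonal Vpd rise in early-to-mid summer, so
  # across shifts the pooled mean of vpd_mean_W3 must not decrease
  cc <- small_study()
  dat <- cc$dat
  trials <- dat$trials
  sy <- aggregate_state_year(trials, dat$features,
                             coords = data.frame(state = cc$cfg$states$state,
                                                 latitude = cc$cfg$states$latitude,
                                                 longitude = cc$cfg$states$longitude))
  by_loc <- split(dat$weather, dat$weather$location_id)
  shifts <- seq(-30, 30, 10)
  mean_vpd3 <- vapply(shifts, function(s) {
    v <- mapply(function(i) {
      st <- sy$state[i]; yr <- sy$year[i]
      anchor <- round(sy$mean_sowing_doy[i])
      locs <- unique(trials$location_id[trials$state == st & trials$year == yr])
      mean(vapply(locs, function(lc) {
        shift_features(by_loc[[lc]], anchor, s, sowing_year = yr)$vpd_mean_W3
      }, numeric(1)))
    }, seq_len(nrow(sy)))
    mean(v)
  }, numeric(1))
  expect_true(all(diff(mean_vpd3) > -0.02))
})
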