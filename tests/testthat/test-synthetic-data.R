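test_that("weather generation is seed-reproducible and latitude-sensible", {
  locs <- data.frame(location_id = c("N1", "S1"), state = c("MN", "LA"),
                     latitude = c(46, 31), longitude = c(-94.5, -92),
                     t0 = c(225, 190), p1 = c(187, 152))
  a <- gen_daily_weather(locs, 2010, seed = 5)
  b <- gen_daily_weather(locs, 2010, seed = 5)
  expect_identical(a, b)
  c2 <- gen_daily_weather(locs, 2010, seed = 6)
  expect_false(identical(a, c2))
  # northern spring minima are colder than southern
  spring <- a$doy %in% 90:150
  expect_lt(mean(a$tmin[spring & a$location_id == "N1"]),
            mean(a$tmin[spring & a$location_id == "S1"]))
  # generated weather satisfies the reader's invariants
  expect_true(all(a$tmax >= a$tmin))
  expect_true(all(a$precip >= 0))
  expect_true(all(a$vp >= 0))
  expect_equal(nrow(a), 2 * 365)
})

test_that("generated datasets pass the package readers unchanged", {
  cc <- small_study()
  d <- withr::local_tempdir()
  simulate_dataset(seed = 42L, config = cc$cfg, out_dir = d)
  expect_silent(w <- read_daily_weather(file.path(d, "weather.csv")))
  expect_silent(tr <- read_trials(file.path(d, "trials.csv")))
  expect_silent(pg <- read_crop_progress(file.path(d, "progress.csv")))
  tabs <- read_state_tables(file.path(d, "econ.csv"), file.path(d, "cpi.csv"))
  expect_equal(sort(unique(tr$state)), sort(cc$cfg$states$state))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_length(truth$states, nrow(cc$cfg$states))
  # one trial per state x year x location, each reporting 2-3 maturity
  # groups (neighbors collapse at the MG-scale boundary)
  n_trials <- nrow(cc$cfg$states) * length(cc$cfg$years) *
    cc$cfg$trials_per_state_year
  expect_equal(length(unique(tr$trial_id)), n_trials)
  expect_true(all(table(tr$trial_id) %in% 2:3))
})

test_that("the dominant maturity group carries the maximum yield", {
  cc <- small_study()
  long <- cc$dat$trials_long
  best <- collapse_trials(long)
  merged <- merge(best, cc$dat$trials, by = "trial_id",
                  suffixes = c("_got", "_planted"))
  expect_equal(merged$yield_kg_ha_got, merged$yield_kg_ha_planted)
  expect_equal(merged$mg_got, merged$mg_planted)
})

test_that("planted window effects are recoverable from the trial table", {
  cc <- small_study()
  tf <- merge(cc$dat$trials, cc$dat$features, by = "trial_id")
  fit <- lm(yield_kg_ha ~ vpd_mean_W3 + vpd_mean_Wpre + precip_cum_W3 +
              factor(state) + year, data = tf)
  ci <- confint(fit, "vpd_mean_W3")
  expect_gt(-1135, ci[1])
  expect_lt(-1135, ci[2])
  ci3 <- confint(fit, "precip_cum_W3")
  expect_gt(7, ci3[1]); expect_lt(7, ci3[2])
})

test_that("the recorded truth is concave with optima inside the grid", {
  cc <- small_study()
  tr <- cc$dat$truth
  expect_s3_class(tr$states, "data.frame")
  expect_true(all(tr$states$opt_shift >= -30 & tr$states$opt_shift <= 30))
  expect_true(all(tr$states$gain_kg_ha >= 0))
  expect_true(all(tr$states$yield_at_typical > 0))
})

test_that("full-scale truth plants the intended national conditions", {
  cfg <- sim_config()
  tr <- synthetic_truth(cfg)
  expect_equal(nrow(tr$states), 27)
  # production-weighted mean optimum of the earlier-is-better states
  expect_gt(tr$national$mean_shift_days, -14)
  expect_lt(tr$national$mean_shift_days, -10)
  expect_gt(tr$national$total_yield_change_pct, 2)
  expect_lt(tr$national$total_yield_change_pct, 6)
  # Texas and Mississippi are the later-is-better states
  pos <- tr$states$state[tr$states$opt_shift > 0]
  expect_setequal(pos, c("TX", "MS"))
  # per-state gains span the reported scale of tens to hundreds of kg/ha
  expect_gt(min(tr$states$gain_kg_ha), 10)
  expect_lt(max(tr$states$gain_kg_ha), 900)
})

test_that("economics tables are consistent and CPI anchors at 2016", {
  cc <- small_study()
  expect_equal(cc$dat$cpi$deflator_to_2016,
               1 + 0.017 * (2016 - cc$dat$cpi$year), tolerance = 1e-12)
  full_cpi <- gen_econ_tables(cc$dat$truth, cc$cfg, seed = 1)$cpi
  expect_true(all(full_cpi$deflator_to_2016 >= 1))
  expect_true(all(cc$dat$econ$production_t > 0))
  expect_true(all(cc$dat$econ$hectares > 0))
  expect_equal(cc$dat$econ$income_usd / cc$dat$econ$production_t,
               rep(unique(cc$dat$econ$income_usd / cc$dat$econ$production_t)[1],
                   nrow(cc$dat$econ)), tolerance = 1e-9)
})

test_that("frost climatologies put the screening margin in the north", {
  cfg <- sim_config()
  tr <- synthetic_truth(cfg)
  locs <- gen_locations(tr, cfg, seed = 8)
  fh <- gen_frost_histories(locs, 46, seed = 9)
  sow <- data.frame(location_id = locs$location_id,
                    sowing_doy = tr$states$sowing_doy[match(locs$state,
                                                            tr$states$state)])
  prof <- frost_profiles(fh, sow, shifts = -21L, thresholds = 0)
  sc <- screen_locations(prof)
  frac <- sc$summary$frac_exceeding
  expect_lt(frac, 0.10)  # only a small northern fringe exceeds 20%
  flagged <- sc$verdicts$location_id[sc$verdicts$exceeds]
  if (length(flagged)) {
    flagged_states <- locs$state[match(flagged, locs$location_id)]
    expect_true(all(flagged_states %in% c("MN", "ND", "SD", "WI", "MI")))
  }
  # at the typical date no location fails the screen
  prof0 <- frost_profiles(fh, sow, shifts = 0L, thresholds = 0)
  expect_equal(screen_locations(prof0)$summary$frac_exceeding, 0)
})

test_that("planted tree data drive the first split to W3 Vpd near 2.44", {
  g <- gen_citree_dataset(n = 186, seed = 1)
  tree <- fit_citree(g$data[, tree_predictor_names()], g$data$yield,
                     citree_controls(n_perm = 1999, seed = 1))
  root <- tree$nodes[tree$nodes$id == 1, ]
  expect_equal(root$split_var, "vpd_mean_W3")
  expect_lt(abs(root$threshold - 2.44), 0.25)
})
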