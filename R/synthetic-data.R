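#' Reference table of the 27 soybean states emulated by the generator
#'
#' Approximate state centroid coordinates, relative non-irrigated
#' production (million tonnes, 2007-2016 scale), typical sowing
#' day-of-year, and the target optimal sowing shift planted in the
#' synthetic weather seasonality. Production weights make the weighted
#' mean of the negative-side target optima about -12 days, with Texas
#' and Mississippi planted as the two later-is-better states.
#'
#' @return Data frame `state, latitude, longitude, production_mt,
#'   sowing_doy, opt_target`.
#' @export
soy_state_table <- function() {
  tab <- read.table(header = TRUE, text = "
state latitude longitude production_mt sowing_doy opt_target
IL 40.0  -89.0 13.00 135  -9
IA 42.0  -93.5 12.50 130  -8
MN 46.0  -94.5  8.50 135 -13
IN 40.0  -86.3  7.50 135  -9
NE 41.5  -99.5  7.00 132  -8
OH 40.3  -82.8  6.50 136  -9
MO 38.5  -92.5  5.50 140 -11
SD 44.5 -100.0  4.50 138 -14
ND 47.0 -100.5  4.00 142 -19
KS 38.5  -98.0  3.50 140 -12
AR 34.8  -92.2  3.30 130 -24
MS 32.7  -89.7  2.20 115   6
WI 44.5  -89.8  2.20 136  -8
MI 44.3  -85.5  2.00 138 -12
KY 37.5  -85.3  1.80 140 -14
TN 35.8  -86.4  1.50 135 -22
LA 31.0  -92.0  1.20 110 -28
NC 35.5  -79.4  0.90 140 -28
VA 37.5  -78.8  0.70 145 -25
PA 40.9  -77.8  0.60 140 -15
SC 33.9  -80.9  0.45 142 -29
OK 35.5  -97.5  0.40 145 -20
AL 32.8  -86.8  0.38 135 -30
GA 32.6  -83.4  0.33 140 -30
TX 31.0  -98.5  0.30 105  30
DE 39.0  -75.5  0.25 140 -18
FL 30.4  -84.3  0.06 130 -30
", stringsAsFactors = FALSE)
  tab
}

#' Default synthetic-study configuration
#'
#' The default scale mirrors the real study design: 27 states observed
#' over 10 years (2007-2016) with 5 trial locations per state (about
#' 1,350 trials), a -30..+30 day shift grid in 10-day steps, 46-year
#' frost climatologies, and planted yield-response coefficients of
#' -1135 kg/ha per kPa of W3 (61-90 days after sowing) mean Vpd,
#' -350 kg/ha/kPa of pre-sowing Vpd, and +7 kg/ha per mm of W3
#' precipitation, on a baseline chosen so state-year yields land near 3,500 kg/ha, with a 30 kg/ha/year
#' technology trend.
#'
#' @param n_states Number of states (first `n_states` rows of
#'   [soy_state_table()], which is ordered by production).
#' @param years Calendar years of the trial program.
#' @param trials_per_state_year Trial locations per state (one trial per
#'   location per year).
#' @param shifts Sowing-shift grid (days).
#' @param frost_years Number of years in each frost climatology.
#' @param coef_vpd_w3,coef_vpd_wpre,coef_precip_w3 Planted window-effect
#'   coefficients (kg/ha per kPa, kg/ha per kPa, kg/ha per mm).
#' @param baseline,baseline_lat_slope,trend Baseline yield (kg/ha), its
#'   latitudinal tilt (kg/ha per degree north of 40 N; negative lifts
#'   southern baselines, reflecting non-weather agronomic gradients),
#'   and the technology trend (kg/ha/year).
#' @param sd_state,sd_state_year,sd_trial Noise standard deviations
#'   (kg/ha) for the state, state-year and trial levels.
#' @param national_gain_target_usd Headline scale for the economics
#'   tables: income levels are set so the expected national cumulative
#'   monetary gain at the planted optima is about this many 2016 US$.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_states = 27L, years = 2007:2016,
                       trials_per_state_year = 5L,
                       shifts = seq(-30L, 30L, by = 10L),
                       frost_years = 46L,
                       coef_vpd_w3 = -1135, coef_vpd_wpre = -350,
                       coef_precip_w3 = 7,
                       baseline = 3000, baseline_lat_slope = -120, trend = 30,
                       sd_state = 100, sd_state_year = 120, sd_trial = 250,
                       national_gain_target_usd = 9e9) {
  states <- soy_state_table()
  stopifnot(n_states >= 1, n_states <= nrow(states))
  states <- states[seq_len(n_states), , drop = FALSE]
  structure(list(states = states, years = years,
                 trials_per_state_year = as.integer(trials_per_state_year),
                 shifts = as.integer(shifts), frost_years = as.integer(frost_years),
                 coef = c(vpd_w3 = coef_vpd_w3, vpd_wpre = coef_vpd_wpre,
                          precip_w3 = coef_precip_w3),
                 baseline = baseline, baseline_lat_slope = baseline_lat_slope,
                 trend = trend,
                 sd_state = sd_state, sd_state_year = sd_state_year,
                 sd_trial = sd_trial,
                 national_gain_target_usd = national_gain_target_usd),
            class = "sim_config")
}

# ---------------------------------------------------------------------------
# Deterministic seasonal skeleton. The same noise-free curves drive both the
# weather simulator and the recorded ground truth, so planted effects travel
# through exactly the feature definitions the pipeline computes.

# Per-state seasonal parameters derived from latitude; t0 (onset of the
# steep early-summer Vpd rise) and p1 (onset of the summer precipitation
# regime) are calibrated per state against the target optimum.
.season_params <- function(lat, t0 = NA_real_, p1 = NA_real_) {
  tamp <- 9 + 0.45 * (lat - 30)
  tsteep <- 6
  peak <- 33 - 0.4 * (lat - 30)
  list(
    tbar = peak - tamp - tsteep, tamp = tamp,
    tsteep = tsteep, ttau = 4,
    t0 = t0,
    drange0 = 12, dsteep = 4,          # diurnal range widens as air dries
    p_lo = 0.12, p_hi = 0.52,          # wet-day probability regimes
    m_lo = 4, m_hi = 15,               # wet-day mean intensity (mm)
    p1 = p1, ptau = 4,
    p2_gap = 95, p2tau = 10, dry_frac = 0.45,  # late-summer dry-down
    season_sd = 5,  # sd (days) of the common inter-annual onset anomaly
    gamma_shape = 0.55,
    dpd = 1.8,                         # dew-point depression below tmin (degC)
    lat = lat
  )
}

.skel_tmax <- function(doy, par) {
  par$tbar + par$tamp * cos(2 * pi * (doy - 200) / 365) +
    par$tsteep * tanh((doy - par$t0) / par$ttau)
}
.skel_drange <- function(doy, par) {
  par$drange0 + par$dsteep * tanh((doy - par$t0) / par$ttau)
}
.skel_tmin <- function(doy, par) .skel_tmax(doy, par) - .skel_drange(doy, par)

# 7-node Gauss-Hermite rule used for all Gaussian expectations below.
.gh7 <- list(
  nodes = c(-2.6519613568352334, -1.673551628767471, -0.8162878828589647, 0,
            0.8162878828589647, 1.673551628767471, 2.6519613568352334),
  weights = c(0.0009717812450995192, 0.05451558281912703, 0.4256072526101278,
              0.8102646175568073, 0.4256072526101278, 0.05451558281912703,
              0.0009717812450995192) / sqrt(pi))

# expectation of es(T + eps), eps ~ N(0, sd^2); es is convex, so this
# exceeds es(T) and the gap grows with temperature - the expected Vpd of
# the noisy generator is *not* the Vpd of the noise-free curve
.es_smooth <- function(t, sd) {
  acc <- 0
  for (k in seq_along(.gh7$nodes)) {
    acc <- acc + .gh7$weights[k] *
      saturation_vapor_pressure(t + sqrt(2) * sd * .gh7$nodes[k])
  }
  acc
}

# expected daily Vpd under the generator's daily noise (tmax AR(1)
# innovations, sd 2.2; tmin adds independent diurnal-range noise, sd 3)
.skel_vpd <- function(doy, par) {
  .es_smooth(.skel_tmax(doy, par), 2.2) -
    .es_smooth(.skel_tmin(doy, par), sqrt(2.2^2 + 3^2))
}
.skel_dry_down <- function(doy, par) {
  1 - par$dry_frac * stats::plogis((doy - (par$p1 + par$p2_gap)) / par$p2tau)
}
.skel_wetp <- function(doy, par) {
  (par$p_lo + (par$p_hi - par$p_lo) * stats::plogis((doy - par$p1) / par$ptau)) *
    .skel_dry_down(doy, par)
}
.skel_wetmean <- function(doy, par) {
  par$m_lo + (par$m_hi - par$m_lo) * stats::plogis((doy - par$p1) / par$ptau)
}
.skel_eprecip <- function(doy, par) .skel_wetp(doy, par) * .skel_wetmean(doy, par)

# Expected (noise-free) response-relevant features at sowing day s:
# W3 mean Vpd, Wpre mean Vpd, W3 cumulative precipitation.
.expected_features <- function(par, s) {
  w3 <- (s + 60):(s + 89)
  wpre <- (s - 30):(s - 1)
  c(vpd_w3 = mean(.skel_vpd(w3, par)),
    vpd_wpre = mean(.skel_vpd(wpre, par)),
    precip_w3 = sum(.skel_eprecip(w3, par)))
}

# Expected yield response (relative scale) over a shift grid for one
# fixed seasonal-onset anomaly.
.expected_response_at <- function(par, s0, shifts, coef, anomaly = 0) {
  p <- par
  p$t0 <- par$t0 + anomaly
  p$p1 <- par$p1 + anomaly
  vapply(shifts, function(u) {
    f <- .expected_features(p, s0 + u)
    coef[["vpd_w3"]] * f[["vpd_w3"]] +
      coef[["vpd_wpre"]] * f[["vpd_wpre"]] +
      coef[["precip_w3"]] * f[["precip_w3"]]
  }, numeric(1))
}

# Marginal expected response: Gauss-Hermite quadrature over the Gaussian
# inter-annual onset anomaly. This, not the anomaly-free curve, is the
# mean response of the generative system, because the response is a
# nonlinear function of the onsets.
.expected_response <- function(par, s0, shifts, coef) {
  acc <- 0
  for (k in seq_along(.gh7$nodes)) {
    a <- sqrt(2) * par$season_sd * .gh7$nodes[k]
    acc <- acc + .gh7$weights[k] * .expected_response_at(par, s0, shifts, coef, a)
  }
  acc
}

# Vertex of the least-squares quadratic through (shifts, y), clipped.
.quad_vertex <- function(shifts, y, lo = -30, hi = 30) {
  q <- stats::lm(y ~ shifts + I(shifts^2))
  b <- stats::coef(q)[2]; c2 <- stats::coef(q)[3]
  if (is.na(c2) || c2 >= 0) {
    v <- if (b < 0) lo else hi
  } else {
    v <- min(max(-b / (2 * c2), lo), hi)
  }
  gain <- (b * v + c2 * v^2) - 0
  list(vertex = unname(v), gain = unname(gain),
       linear = unname(b), quadratic = unname(c2))
}

# Calibrate the seasonal onsets t0 (Vpd rise) and p1 (precip regime) so
# the quadratic vertex of the expected response on the shift grid lands
# on the state's target optimum. Deterministic grid search.
.calibrate_state <- function(lat, s0, target, shifts, coef, p_gap = 38) {
  cand <- seq(s0 + 20, s0 + 150, by = 1)
  best <- NULL; best_err <- Inf
  for (t0 in cand) {
    par <- .season_params(lat, t0 = t0, p1 = t0 - p_gap)
    B <- .expected_response(par, s0, shifts, coef)
    qv <- .quad_vertex(shifts, B)
    err <- abs(qv$vertex - target)
    if (err < best_err) { best_err <- err; best <- list(par = par, qv = qv) }
  }
  best
}

#' Planted ground truth of the synthetic study
#'
#' Calibrates each state's seasonal weather parameters so the expected
#' yield response over the shift grid (computed through the same window
#' feature definitions the pipeline uses, from the noise-free seasonal
#' curves) has its quadratic-fit optimum at the state's target shift,
#' then records the resulting per-state optima, gains and response
#' curvature together with the planted coefficients. This is recorded
#' before any pipeline stage runs and is serialized with every
#' generated dataset.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_truth` with elements `states` (data
#'   frame: state, seasonal onsets, `opt_shift`, `gain_kg_ha`,
#'   `pct_gain`, quadratic coefficients), `coef`, `trend`, `baseline`,
#'   `noise`, and `national` (production-weighted mean negative-side
#'   optimum and percent gain).
#' @export
synthetic_truth <- function(config = sim_config()) {
  st <- config$states
  rows <- vector("list", nrow(st))
  trend_mid <- config$trend * (mean(config$years) - config$years[1])
  for (i in seq_len(nrow(st))) {
    cal <- .calibrate_state(st$latitude[i], st$sowing_doy[i], st$opt_target[i],
                            config$shifts, config$coef)
    b0 <- .expected_response(cal$par, st$sowing_doy[i], 0, config$coef)
    y0 <- config$baseline +
      config$baseline_lat_slope * (st$latitude[i] - 40) + trend_mid + b0
    rows[[i]] <- data.frame(
      state = st$state[i], latitude = st$latitude[i],
      sowing_doy = st$sowing_doy[i],
      t0 = cal$par$t0, p1 = cal$par$p1,
      opt_shift = cal$qv$vertex, gain_kg_ha = cal$qv$gain,
      yield_at_typical = y0,
      pct_gain = cal$qv$gain / y0,
      resp_linear = cal$qv$linear, resp_quadratic = cal$qv$quadratic,
      stringsAsFactors = FALSE)
  }
  states <- do.call(rbind, rows)
  w <- st$production_mt
  neg <- states$opt_shift <= 0
  national <- list(
    mean_shift_days = sum(states$opt_shift[neg] * w[neg]) / sum(w[neg]),
    total_yield_change_pct = 100 * sum(states$pct_gain[neg] * w[neg]) / sum(w[neg])
  )
  structure(list(states = states, coef = as.list(config$coef),
                 baseline = config$baseline, trend = config$trend,
                 noise = list(sd_state = config$sd_state,
                              sd_state_year = config$sd_state_year,
                              sd_trial = config$sd_trial),
                 national = national),
            class = "synthetic_truth")
}

# ---------------------------------------------------------------------------
# Stochastic generators

# Daylength (seconds) from latitude and day of year (standard declination
# formula; clamped for polar edge cases).
.daylength_s <- function(lat, doy) {
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  latr <- lat * pi / 180
  cosH <- pmin(1, pmax(-1, -tan(latr) * tan(decl)))
  2 * acos(cosH) / (2 * pi) * 86400
}

.ar1 <- function(n, sd, rho) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.vector(stats::filter(e, rho, method = "recursive"))
}

#' Generate daily weather for a set of locations
#'
#' Daily maximum temperature follows each location's seasonal skeleton
#' (annual sinusoid plus a calibrated steep early-summer rise) with
#' AR(1) noise; the diurnal range widens with the dry season;
#' precipitation is wet-day occurrence times gamma intensities whose
#' probability and mean follow a calibrated seasonal regime change;
#' vapor pressure derives from a dew-point offset below the daily
#' minimum; solar radiation is an annual sinusoid with noise; day length
#' is deterministic from latitude. One 365-day record per location-year;
#' reproducible from the seed.
#'
#' @param locations Data frame `location_id, state, latitude, longitude,
#'   t0, p1` (seasonal onsets from [synthetic_truth()]).
#' @param years Vector of calendar years.
#' @param seed Integer seed.
#' @return Daily weather data frame in the internal schema (vp in kPa).
#' @export
gen_daily_weather <- function(locations, years, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  doy <- 1:365
  out <- vector("list", nrow(locations) * length(years))
  k <- 0L
  for (i in seq_len(nrow(locations))) {
    par <- .season_params(locations$latitude[i], t0 = locations$t0[i],
                          p1 = locations$p1[i])
    dayl <- .daylength_s(locations$latitude[i], doy)
    srad0 <- 14 + 9 * cos(2 * pi * (doy - 172) / 365) - 0.15 * (locations$latitude[i] - 38)
    for (yr in years) {
      k <- k + 1L
      # inter-annual anomalies: the onset of the hot/dry season and of the
      # summer precipitation regime move together from year to year (with
      # some independent drift), and whole summers are more or less humid;
      # these anomalies are the dominant real-world source of year-to-year
      # weather contrast at fixed location
      season_jit <- stats::rnorm(1, 0, par$season_sd)
      parY <- par
      parY$t0 <- par$t0 + season_jit
      parY$p1 <- par$p1 + season_jit
      tmax0 <- .skel_tmax(doy, parY)
      dr0 <- .skel_drange(doy, parY)
      wetp <- .skel_wetp(doy, parY)
      wetm <- .skel_wetmean(doy, parY)
      dpd_year <- stats::rnorm(1, 0, 2)
      tmax <- tmax0 + .ar1(365, 2.2, 0.65)
      tmin <- tmax - pmax(0.5, dr0 + stats::rnorm(365, 0, 3))
      wet <- stats::runif(365) < wetp
      amt <- ifelse(wet,
                    stats::rgamma(365, shape = par$gamma_shape,
                                  scale = wetm / par$gamma_shape), 0)
      # dew-point depression fluctuates substantially day to day (air-mass
      # changes), which decouples humidity from the temperature curve
      vp <- saturation_vapor_pressure(
        tmin - pmax(0, par$dpd + dpd_year + .ar1(365, 4, 0.5)))
      srad <- pmax(1, srad0 + stats::rnorm(365, 0, 2))
      out[[k]] <- data.frame(
        location_id = locations$location_id[i],
        latitude = locations$latitude[i], longitude = locations$longitude[i],
        year = yr, doy = doy,
        tmin = tmin, tmax = tmax, precip = amt, srad = srad,
        vp = vp, dayl = dayl, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate trial locations for every state
#'
#' `trials_per_state_year` locations per state, jittered around the
#' state centroid; the calibrated seasonal onsets are shared within a
#' state.
#' @param truth A [synthetic_truth()] object.
#' @param config The matching [sim_config()].
#' @param seed Integer seed.
#' @return Data frame `location_id, state, latitude, longitude, t0, p1`.
#' @export
gen_locations <- function(truth, config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  st <- merge(config$states, truth$states[, c("state", "t0", "p1")], by = "state")
  rows <- lapply(seq_len(nrow(st)), function(i) {
    nl <- config$trials_per_state_year
    data.frame(
      location_id = sprintf("%s_%02d", st$state[i], seq_len(nl)),
      state = st$state[i],
      latitude = st$latitude[i] + stats::runif(nl, -0.7, 0.7),
      longitude = st$longitude[i] + stats::runif(nl, -1.2, 1.2),
      t0 = st$t0[i], p1 = st$p1[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the trial-yield table from weather and planted truth
#'
#' One trial per location per year. The trial's sowing day jitters
#' around the state's typical date; yield is built from the trial's own
#' window features (computed from the generated weather via the
#' pipeline's feature definitions) with the planted coefficients, a
#' common baseline, a technology trend, and state, state-year, and
#' trial-level Gaussian noise. Feature terms are centered at each
#' state's expected shift-0 values so state mean yields are comparable
#' and the planted slopes are not confounded with between-state level
#' differences. Three maturity groups are reported per trial, the
#' dominant one highest.
#'
#' @param weather Generated daily weather ([gen_daily_weather()]).
#' @param locations Location table ([gen_locations()]).
#' @param truth A [synthetic_truth()] object.
#' @param config The matching [sim_config()].
#' @param seed Integer seed.
#' @return List with `trials_long` (reader schema, one row per MG),
#'   `trials` (one row per trial with the dominant-MG yield), and
#'   `features` (per-trial window features).
#' @export
gen_trials <- function(weather, locations, truth, config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  st <- truth$states
  years <- config$years
  coef <- config$coef

  # trial design: sowing dates. Within a state, the trial sites sow on a
  # staggered schedule spanning about six weeks around the typical date
  # (site logistics plus deliberate planting-date staggering), as in
  # real cultivar-trial programs; this spread is also what lets a
  # predictive model learn the seasonal gradient that counterfactual
  # sowing shifts traverse.
  n_loc_per_state <- config$trials_per_state_year
  design <- do.call(rbind, lapply(seq_len(nrow(locations)), function(i) {
    s0 <- st$sowing_doy[match(locations$state[i], st$state)]
    loc_rank <- as.integer(sub(".*_", "", locations$location_id[i]))
    stagger <- if (n_loc_per_state > 1) {
      -20 + 40 * (loc_rank - 1) / (n_loc_per_state - 1)
    } else 0
    data.frame(location_id = locations$location_id[i],
               state = locations$state[i], year = years,
               sowing_doy = pmax(61L, as.integer(round(
                 s0 + stagger + stats::rnorm(length(years), 0, 3)))),
               stringsAsFactors = FALSE)
  }))
  design$trial_id <- sprintf("T%04d", seq_len(nrow(design)))

  feats <- build_trial_features(weather, design)
  f <- merge(design, feats, by = "trial_id")

  # The window effects act on the raw features, so between-state yield
  # level differences are the honest consequence of between-state
  # climate differences (hot, high-Vpd states yield less), exactly the
  # structure an additive model in weather features can represent.
  state_eff <- stats::setNames(stats::rnorm(nrow(st), 0, config$sd_state), st$state)
  sy_key <- unique(paste(f$state, f$year))
  sy_eff <- stats::setNames(stats::rnorm(length(sy_key), 0, config$sd_state_year),
                            sy_key)

  lat_s <- st$latitude[match(f$state, st$state)]
  mu <- config$baseline +
    config$baseline_lat_slope * (lat_s - 40) +
    state_eff[f$state] +
    config$trend * (f$year - years[1]) +
    coef[["vpd_w3"]] * f$vpd_mean_W3 +
    coef[["vpd_wpre"]] * f$vpd_mean_Wpre +
    coef[["precip_w3"]] * f$precip_cum_W3 +
    sy_eff[paste(f$state, f$year)]
  yield <- pmax(300, mu + stats::rnorm(nrow(f), 0, config$sd_trial))

  trials <- data.frame(trial_id = f$trial_id, state = f$state, year = f$year,
                       location_id = f$location_id, sowing_doy = f$sowing_doy,
                       mg = NA_character_, yield_kg_ha = as.numeric(yield),
                       stringsAsFactors = FALSE)

  # maturity groups: dominant MG by latitude, two neighbors yielding less
  lat <- locations$latitude[match(trials$location_id, locations$location_id)]
  mg_num <- pmin(8, pmax(0, round((46 - lat) / 2)))
  trials$mg <- paste0("MG", mg_num)
  long <- do.call(rbind, lapply(c(0L, -1L, 1L), function(dmg) {
    d <- trials
    d$mg <- paste0("MG", pmin(8, pmax(0, mg_num + dmg)))
    if (dmg != 0L) {
      d$yield_kg_ha <- pmax(100, d$yield_kg_ha - stats::runif(nrow(d), 100, 400))
    }
    d
  }))
  long <- long[!duplicated(paste(long$trial_id, long$mg)), , drop = FALSE]
  long <- long[order(long$trial_id, long$mg), , drop = FALSE]
  rownames(long) <- NULL

  list(trials_long = long[, c("trial_id", "state", "year", "location_id",
                              "sowing_doy", "mg", "yield_kg_ha")],
       trials = trials, features = feats)
}

#' Generate weekly crop-progress tables
#'
#' Cumulative percent of hectares sown follows a logistic around each
#' state's typical sowing date, reported weekly.
#' @param truth A [synthetic_truth()] object.
#' @param config The matching [sim_config()].
#' @param seed Integer seed.
#' @return Data frame `state, year, doy, pct_sown`.
#' @export
gen_crop_progress <- function(truth, config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  st <- truth$states
  rows <- list()
  for (i in seq_len(nrow(st))) {
    for (yr in config$years) {
      mid <- st$sowing_doy[i] + stats::rnorm(1, 0, 3)
      doy <- as.integer(round(mid + seq(-21, 21, by = 7)))
      pct <- round(100 * stats::plogis((doy - mid) / 5), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        state = st$state[i], year = yr, doy = doy, pct_sown = pct,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate multi-decade daily-minimum-temperature histories for frost risk
#'
#' Spring (day-of-year 40..200) daily minimum temperatures per location
#' and year: a latitude-dependent warming trend through spring with
#' AR(1) noise, calibrated so that at 21-days-earlier sowing a small
#' fraction of the northernmost locations sit above the 20% frost
#' (tmin < 0) probability at emergence.
#'
#' @param locations Location table ([gen_locations()]).
#' @param years Number of years of history (default 46, 1981-2016).
#' @param seed Integer seed.
#' @return Data frame `location_id, year, doy, tmin`.
#' @export
gen_frost_histories <- function(locations, years = 46L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  doy <- 40:200
  yrs <- seq(2016 - years + 1, 2016)
  out <- vector("list", nrow(locations) * length(yrs))
  k <- 0L
  for (i in seq_len(nrow(locations))) {
    lat <- locations$latitude[i]
    # spring minimum-temperature climatology: latitude gradient, ~0.22
    # degC/day spring warm-up, and a per-location microclimate offset
    base <- 14.3 - 0.9 * (lat - 35) + 0.22 * (doy - 120) +
      stats::rnorm(1, 0, 1)
    for (yr in yrs) {
      k <- k + 1L
      out[[k]] <- data.frame(location_id = locations$location_id[i],
                             year = yr, doy = doy,
                             tmin = base + .ar1(length(doy), 3.4, 0.6),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate state economics and CPI tables
#'
#' Production follows the state production weights with mild year
#' noise; hectares assume about 3 t/ha; the CPI deflator declines
#' linearly to 1 in 2016. Income per tonne is a constant price chosen
#' so that the expected national cumulative monetary gain at the
#' planted optima matches the configured headline scale.
#'
#' @param truth A [synthetic_truth()] object.
#' @param config The matching [sim_config()].
#' @param seed Integer seed.
#' @return List with `econ` (`state, year, income_usd, production_t,
#'   hectares`) and `cpi` (`year, deflator_to_2016`).
#' @export
gen_econ_tables <- function(truth, config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  st <- config$states
  years <- config$years
  cpi <- data.frame(year = years,
                    deflator_to_2016 = 1 + 0.017 * (2016 - years))
  # price solving expected cumulative gain ~= target
  pct <- truth$states$pct_gain[match(st$state, truth$states$state)]
  exp_gain_per_price <- sum(st$production_mt * 1e6 * pct) *
    length(years) * mean(cpi$deflator_to_2016)
  price <- config$national_gain_target_usd / exp_gain_per_price
  econ <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    prod_t <- st$production_mt[i] * 1e6 * (1 + stats::rnorm(length(years), 0, 0.05))
    data.frame(state = st$state[i], year = years,
               income_usd = prod_t * price,
               production_t = prod_t,
               hectares = prod_t / 3.0, stringsAsFactors = FALSE)
  }))
  rownames(econ) <- NULL
  list(econ = econ, cpi = cpi, price_usd_per_t = price)
}

#' Generate a complete synthetic study with recorded ground truth
#'
#' One call produces every input the pipeline reads - daily weather,
#' trial yields (long MG format), crop progress, economics and CPI
#' tables, frost histories - together with the planted ground truth, so
#' every recovery test is executable from this single entry point.
#' All randomness derives from `seed`.
#'
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @param out_dir Optional directory: when given, all tables are written
#'   as CSV plus `truth.json`.
#' @return List with `weather`, `locations`, `trials_long`, `trials`,
#'   `features`, `progress`, `econ`, `cpi`, `frost_histories`,
#'   `frost_sowing`, `truth`, and `config`.
#' @export
simulate_dataset <- function(seed = 1L, config = sim_config(), out_dir = NULL) {
  truth <- synthetic_truth(config)
  locations <- gen_locations(truth, config, seed = seed)
  weather <- gen_daily_weather(locations, config$years, seed = seed + 1L)
  tr <- gen_trials(weather, locations, truth, config, seed = seed + 2L)
  progress <- gen_crop_progress(truth, config, seed = seed + 3L)
  econ <- gen_econ_tables(truth, config, seed = seed + 4L)
  frost <- gen_frost_histories(locations, config$frost_years, seed = seed + 5L)
  frost_sowing <- data.frame(
    location_id = locations$location_id,
    sowing_doy = truth$states$sowing_doy[match(locations$state,
                                               truth$states$state)],
    stringsAsFactors = FALSE)
  out <- list(weather = weather, locations = locations,
              trials_long = tr$trials_long, trials = tr$trials,
              features = tr$features, progress = progress,
              econ = econ$econ, cpi = econ$cpi,
              frost_histories = frost, frost_sowing = frost_sowing,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_daily_weather(weather, file.path(out_dir, "weather.csv"))
    data.table::fwrite(tr$trials_long, file.path(out_dir, "trials.csv"))
    data.table::fwrite(progress, file.path(out_dir, "progress.csv"))
    data.table::fwrite(econ$econ, file.path(out_dir, "econ.csv"))
    data.table::fwrite(econ$cpi, file.path(out_dir, "cpi.csv"))
    data.table::fwrite(frost, file.path(out_dir, "frost_tmin.csv"))
    data.table::fwrite(frost_sowing, file.path(out_dir, "frost_sowing.csv"))
    jsonlite::write_json(
      list(states = truth$states, coef = truth$coef,
           baseline = truth$baseline, trend = truth$trend,
           noise = truth$noise, national = truth$national),
      file.path(out_dir, "truth.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Generate a state-year dataset with a planted tree structure
#'
#' Emulates the qualitative partition structure seen in the national
#' yield analysis: the dominant split is W3 (61-90 days after sowing)
#' mean Vpd at 2.44 kPa; within the high-Vpd branch a pre-sowing Vpd
#' threshold at 1.79 kPa separates the worst drought years; within the
#' low-Vpd branch yields differ by state group and by whether W3
#' precipitation exceeds 75 mm. All remaining tree predictors are
#' independent noise on plausible scales. Used by the split-recovery
#' test suite.
#'
#' @param n Number of state-year records (default 186).
#' @param seed Integer seed.
#' @param sd_noise Residual yield noise (kg/ha).
#' @return List with `data` (data frame of the 31 tree predictors plus
#'   `yield`) and `truth` (the planted thresholds and effects).
#' @export
gen_citree_dataset <- function(n = 186L, seed = 1L, sd_noise = 250) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  states <- soy_state_table()$state
  group1 <- c("AL", "FL", "GA", "IA", "KS", "LA", "MN", "MO", "NC", "ND",
              "OK", "TN", "TX", "VA")
  d <- data.frame(state = factor(sample(states, n, replace = TRUE)))
  num_names <- setdiff(tree_predictor_names(), "state")
  ranges <- list(precip_cum = c(10, 250), srad_cum = c(300, 900),
                 vpd_mean = c(0.8, 3.6), tmax_mean = c(18, 36),
                 rh_mean = c(0.35, 0.95))
  for (nm in num_names) {
    var <- sub("_(Wpre|W[1-5])$", "", nm)
    r <- ranges[[var]]
    d[[nm]] <- stats::runif(n, r[1], r[2])
  }
  thr_vpd3 <- 2.44; thr_vpdpre <- 1.79; thr_precip <- 75
  hi <- d$vpd_mean_W3 > thr_vpd3
  harsh <- hi & d$vpd_mean_Wpre > thr_vpdpre
  g1 <- !hi & (as.character(d$state) %in% group1)
  wet <- !hi & d$precip_cum_W3 > thr_precip
  mu <- 4100 - 1100 * hi - 500 * harsh - 420 * g1 + 320 * wet
  d$yield <- mu + stats::rnorm(n, 0, sd_noise)
  list(data = d,
       truth = list(thr_vpd3 = thr_vpd3, thr_vpdpre = thr_vpdpre,
                    thr_precip = thr_precip, group1 = group1,
                    effects = c(hi = -1100, harsh = -500, group1 = -420,
                                wet = 320), base = 4100))
}
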