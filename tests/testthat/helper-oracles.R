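# Independent oracles and small fixture builders shared across the suite.

# Literal, independent evaluation of the saturation-vapor-pressure curve
# (kept deliberately separate from the package implementation).
es_oracle <- function(t) 0.6107 * exp(17.269 * t / (237.3 + t))

# Brute-force window aggregation: day-by-day loop, no cumulative sums.
# `days` must cover sowing_doy - 30 .. sowing_doy + 149 in one year.
window_oracle <- function(days, sowing_doy) {
  out <- list()
  wins <- list(Wpre = -30:-1, W1 = 0:29, W2 = 30:59, W3 = 60:89,
               W4 = 90:119, W5 = 120:149, season = -30:149)
  for (w in names(wins)) {
    doys <- sowing_doy + wins[[w]]
    rows <- days[match(doys, days$doy), ]
    vpd <- es_oracle(rows$tmax) - es_oracle(rows$tmin)
    rh <- rows$vp / ((es_oracle(rows$tmax) + es_oracle(rows$tmin)) / 2)
    wet <- sum(rows$precip > 1)
    dry <- sum(rows$precip < 1)
    out[[paste0("precip_cum_", w)]] <- sum(rows$precip)
    out[[paste0("srad_cum_", w)]] <- sum(rows$srad)
    out[[paste0("vpd_mean_", w)]] <- mean(vpd)
    out[[paste0("tmax_mean_", w)]] <- mean(rows$tmax)
    out[[paste0("rh_mean_", w)]] <- mean(rh)
    out[[paste0("tmin_mean_", w)]] <- mean(rows$tmin)
    out[[paste0("dayl_mean_", w)]] <- mean(rows$dayl)
    out[[paste0("wet_days_", w)]] <- wet
    out[[paste0("dry_days_", w)]] <- dry
    out[[paste0("ab_ratio_", w)]] <- if (dry == 0) wet / (dry + 1) else wet / dry
    out[[paste0("ab_ratio_flag_", w)]] <- as.numeric(dry == 0)
  }
  unlist(out)
}

# Exhaustive search for the best binary split of numeric x: maximize the
# between-group sum of squares over every admissible cut, by plain loop.
split_oracle <- function(x, y, min_terminal = 1L) {
  o <- order(x); xs <- x[o]; ys <- y[o]; n <- length(y)
  best <- NULL; best_crit <- -Inf
  for (k in seq_len(n - 1L)) {
    if (k < min_terminal || (n - k) < min_terminal) next
    if (xs[k] >= xs[k + 1L]) next
    mL <- mean(ys[1:k]); mR <- mean(ys[(k + 1L):n])
    crit <- k * (n - k) / n * (mL - mR)^2
    if (crit > best_crit) {
      best_crit <- crit
      best <- (xs[k] + xs[k + 1L]) / 2
    }
  }
  best
}

# One location-year of uniform random daily weather over a full year.
random_weather_year <- function(seed, location_id = "L1", year = 2010L) {
  set.seed(seed)
  tmin <- runif(365, -5, 20)
  data.frame(location_id = location_id,
             latitude = 40, longitude = -90, year = year, doy = 1:365,
             tmin = tmin, tmax = tmin + runif(365, 0.5, 15),
             precip = ifelse(runif(365) < 0.4, rgamma(365, 0.7, scale = 8), 0),
             srad = runif(365, 5, 30),
             vp = runif(365, 0.2, 2.5),
             dayl = runif(365, 3e4, 6e4))
}

# Constant-weather series: every day identical.
constant_weather <- function(tmax = 25, tmin = 15, precip = 2, srad = 20,
                             vp = 1.2, dayl = 5e4, year = 2010L) {
  data.frame(location_id = "C1", latitude = 40, longitude = -90,
             year = year, doy = 1:365, tmin = tmin, tmax = tmax,
             precip = precip, srad = srad, vp = vp, dayl = dayl)
}

# Small cached synthetic study (3 states, 3 years, 3 locations/state):
# built once per test run.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_states = 3L, years = 2008:2010,
                       trials_per_state_year = 3L)
      cache <<- list(cfg = cfg, dat = simulate_dataset(seed = 42L, config = cfg))
    }
    cache
  }
})
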