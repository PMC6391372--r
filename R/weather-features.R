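#' Saturation vapor pressure of air
#'
#' Tetens-type saturation vapor pressure curve,
#' \eqn{e_s(T) = 0.6107 \exp(17.269\,T / (237.3 + T))} with \eqn{T} in
#' degrees Celsius and the result in kPa.
#'
#' @param t Air temperature in degrees Celsius. Must be finite and within
#'   the physically meaningful range \[-60, 60\].
#' @return Saturation vapor pressure in kPa, strictly increasing in `t`.
#' @examples
#' saturation_vapor_pressure(0)   # 0.6107
#' saturation_vapor_pressure(25)
#' @export
saturation_vapor_pressure <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("temperature must be finite numeric (degC)", call. = FALSE)
  }
  if (any(t < -60 | t > 60)) {
    stop("temperature outside physical range [-60, 60] degC", call. = FALSE)
  }
  0.6107 * exp(17.269 * t / (237.3 + t))
}

#' Daily vapor pressure deficit from the diurnal temperature range
#'
#' Operational daily Vpd: the difference between saturation vapor pressure
#' at the daily maximum and at the daily minimum temperature. The daily
#' minimum temperature is used as a surrogate for the dew point, so the
#' result is always non-negative.
#'
#' @param tmax,tmin Daily maximum and minimum temperature (degC),
#'   `tmax >= tmin` elementwise.
#' @return Daily vapor pressure deficit in kPa.
#' @export
daily_vpd <- function(tmax, tmin) {
  if (length(tmax) != length(tmin)) {
    stop("tmax and tmin must have equal length", call. = FALSE)
  }
  if (any(tmax < tmin)) {
    bad <- which(tmax < tmin)
    stop("tmax < tmin at position(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  saturation_vapor_pressure(tmax) - saturation_vapor_pressure(tmin)
}

#' Daily relative humidity from actual vapor pressure
#'
#' Actual vapor pressure divided by the mean of saturation vapor pressure
#' at the daily maximum and minimum temperatures. Values above 1 are
#' physically suspect (supersaturation) but are returned as-is with a
#' message, since gridded weather products occasionally produce them.
#'
#' @param vp Actual water vapor pressure, kPa, non-negative.
#' @param tmax,tmin Daily temperature extremes (degC), `tmax >= tmin`.
#' @param quiet Suppress the supersaturation message.
#' @return Relative humidity as a fraction (usually in \[0, 1\]).
#' @export
daily_relative_humidity <- function(vp, tmax, tmin, quiet = FALSE) {
  if (any(vp < 0)) stop("vp must be non-negative", call. = FALSE)
  if (any(tmax < tmin)) stop("tmax < tmin", call. = FALSE)
  rh <- vp / ((saturation_vapor_pressure(tmax) + saturation_vapor_pressure(tmin)) / 2)
  if (!quiet && any(rh > 1)) {
    message("daily_relative_humidity: ", sum(rh > 1),
            " value(s) exceed 1 (supersaturation); returned unmodified")
  }
  rh
}

#' Sowing-relative 30-day window labels
#'
#' The growing season is divided into six successive 30-day windows
#' anchored on the sowing day: one pre-sowing window `Wpre` covering
#' offsets -30..-1 and five post-sowing windows `W1`..`W5` covering
#' 0..29, 30..59, 60..89, 90..119 and 120..149 days after sowing.
#' Windows are half-open 30-day bins; the sowing day itself belongs to
#' `W1`.
#'
#' @return Character vector of the six window labels, in seasonal order.
#' @export
window_labels <- function() c("Wpre", "W1", "W2", "W3", "W4", "W5")

#' Window start offsets (days relative to sowing) for each label.
#' @keywords internal
.window_starts <- function() {
  stats::setNames(c(-30L, 0L, 30L, 60L, 90L, 120L), window_labels())
}

#' Map a sowing-relative day offset to its 30-day window
#'
#' @param day_offset Integer day offset(s) relative to the sowing day
#'   (negative = before sowing).
#' @return Window label (`"Wpre"`, `"W1"`, ..., `"W5"`) or `NA` for
#'   offsets outside \[-30, 149\].
#' @examples
#' window_of(-30)  # "Wpre"
#' window_of(0)    # "W1"
#' window_of(150)  # NA
#' @export
window_of <- function(day_offset) {
  if (any(day_offset != floor(day_offset))) {
    stop("day_offset must be integer-valued", call. = FALSE)
  }
  idx <- floor(day_offset / 30) + 2L
  window_labels()[ifelse(idx >= 1 & idx <= 6, idx, NA_integer_)]
}

# Variables aggregated per window. *_cum are summed over the window;
# *_mean are arithmetic means of the daily value; wet/dry are day counts.
.window_vars <- function() {
  c("precip_cum", "srad_cum", "vpd_mean", "tmax_mean", "rh_mean",
    "tmin_mean", "dayl_mean", "wet_days", "dry_days", "ab_ratio",
    "ab_ratio_flag")
}

#' Names of the candidate predictors for the interpretation tree
#'
#' Five weather variables (cumulative precipitation, cumulative solar
#' radiation, mean Vpd, mean maximum temperature, mean relative humidity)
#' over six sowing-relative windows, plus the categorical state: 31
#' predictors in total. Daily minimum temperature and day length are
#' computed and stored alongside but deliberately excluded here because
#' they confound with the retained variables and the tree is meant for
#' interpretation.
#'
#' @return Character vector of length 31.
#' @export
tree_predictor_names <- function() {
  vars <- c("precip_cum", "srad_cum", "vpd_mean", "tmax_mean", "rh_mean")
  c(as.vector(t(outer(vars, window_labels(), paste, sep = "_"))), "state")
}

#' Names of the numeric predictors used by the boosting model
#'
#' The five tree-stage weather variables over every window and the
#' season, extended with the wet-day count a (precipitation > 1 mm),
#' dry-day count b (< 1 mm) and the ratio a/b, plus latitude, longitude
#' and calendar year. Daily minimum temperature and day length remain
#' excluded, as in the tree stage: besides confounding, day length is a
#' deterministic function of latitude and date, so it carries no
#' identifiable signal in the trial data yet would move strongly under
#' counterfactual sowing shifts. The `ab_ratio_flag` indicator columns
#' are diagnostic only and are not model features.
#'
#' @return Character vector of feature column names.
#' @export
boost_predictor_names <- function() {
  vars <- c("precip_cum", "srad_cum", "vpd_mean", "tmax_mean", "rh_mean",
            "wet_days", "dry_days", "ab_ratio")
  wcols <- as.vector(t(outer(vars, c(window_labels(), "season"), paste, sep = "_")))
  c(wcols, "latitude", "longitude", "year")
}

# Build a cumulative-sum index over one location's contiguous daily
# series so that any 30-day window aggregate is an O(1) difference of
# cumulative sums. `days` must contain one location only.
#' @keywords internal
weather_index <- function(days) {
  req <- c("year", "doy", "tmin", "tmax", "precip", "srad", "vp")
  miss <- setdiff(req, names(days))
  if (length(miss)) {
    stop("weather series missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(days$doy < 1 | days$doy > 365)) {
    stop("doy outside 1..365 (leap days must be dropped on read)", call. = FALSE)
  }
  y0 <- min(days$year)
  t <- (days$year - y0) * 365L + days$doy
  o <- order(t)
  t <- t[o]
  if (anyDuplicated(t)) stop("duplicate (year, doy) in weather series", call. = FALSE)
  d <- days[o, , drop = FALSE]
  vpd <- daily_vpd(d$tmax, d$tmin)
  es2 <- (saturation_vapor_pressure(d$tmax) + saturation_vapor_pressure(d$tmin)) / 2
  rh <- d$vp / es2
  dayl <- if ("dayl" %in% names(d)) d$dayl else rep(NA_real_, nrow(d))
  list(
    year0 = y0,
    t = t,
    t_min = t[1L],
    t_max = t[length(t)],
    contiguous = all(diff(t) == 1L),
    cum = list(
      precip = cumsum(d$precip),
      srad   = cumsum(d$srad),
      vpd    = cumsum(vpd),
      tmax   = cumsum(d$tmax),
      tmin   = cumsum(d$tmin),
      rh     = cumsum(rh),
      dayl   = cumsum(dayl),
      wet    = cumsum(as.numeric(d$precip > 1)),
      dry    = cumsum(as.numeric(d$precip < 1))
    )
  )
}

# Sum of a cumulative array over absolute day positions [a, b] given the
# index's day axis starts at idx$t_min and is contiguous.
.cumrange <- function(cumv, idx, a, b) {
  i0 <- a - idx$t_min + 1L
  i1 <- b - idx$t_min + 1L
  cumv[i1] - if (i0 > 1L) cumv[i0 - 1L] else 0
}

# Feature row (named numeric) for one anchor day (absolute index into the
# location's day axis). Assumes coverage was checked by the caller.
.features_at <- function(idx, anchor_t) {
  starts <- .window_starts()
  labs <- window_labels()
  out <- numeric(0)
  agg_one <- function(a, b, lab) {
    n <- b - a + 1L
    wet <- .cumrange(idx$cum$wet, idx, a, b)
    dry <- .cumrange(idx$cum$dry, idx, a, b)
    flag <- as.numeric(dry == 0)
    ab <- if (dry == 0) wet / (dry + 1) else wet / dry
    v <- c(
      precip_cum = .cumrange(idx$cum$precip, idx, a, b),
      srad_cum   = .cumrange(idx$cum$srad, idx, a, b),
      vpd_mean   = .cumrange(idx$cum$vpd, idx, a, b) / n,
      tmax_mean  = .cumrange(idx$cum$tmax, idx, a, b) / n,
      rh_mean    = .cumrange(idx$cum$rh, idx, a, b) / n,
      tmin_mean  = .cumrange(idx$cum$tmin, idx, a, b) / n,
      dayl_mean  = .cumrange(idx$cum$dayl, idx, a, b) / n,
      wet_days   = wet,
      dry_days   = dry,
      ab_ratio   = ab,
      ab_ratio_flag = flag
    )
    stats::setNames(v, paste(names(v), lab, sep = "_"))
  }
  for (k in seq_along(labs)) {
    a <- anchor_t + starts[[k]]
    out <- c(out, agg_one(a, a + 29L, labs[k]))
  }
  out <- c(out, agg_one(anchor_t - 30L, anchor_t + 149L, "season"))
  out
}

#' Aggregate one location-year of daily weather into sowing-relative windows
#'
#' Reduces a contiguous daily weather series to the six 30-day window
#' feature sets plus season-wide (offsets -30..149) aggregates:
#' cumulative precipitation and solar radiation; means of daily Vpd,
#' maximum temperature, relative humidity, minimum temperature and day
#' length; the count of wet days (precipitation > 1 mm, "a") and dry days
#' (precipitation < 1 mm, "b") and their ratio a/b. Days with
#' precipitation of exactly 1 mm fall in neither count. When b = 0 the
#' ratio is reported as a/(b+1) and the companion `ab_ratio_flag` column
#' is set to 1.
#'
#' The series may span a year boundary (e.g. a pre-sowing window reaching
#' into the previous calendar year); years are treated as 365-day blocks.
#'
#' @param days Data frame of daily records for a single location with
#'   columns `year`, `doy`, `tmin`, `tmax`, `precip`, `srad`, `vp` and
#'   optionally `dayl`.
#' @param sowing_doy Sowing day-of-year (1..365).
#' @param sowing_year Calendar year of sowing; defaults to the earliest
#'   year in `days`.
#' @return A one-row data frame with 77 feature columns named
#'   `<var>_<window>` (windows `Wpre`, `W1`..`W5`, `season`).
#' @export
aggregate_windows <- function(days, sowing_doy, sowing_year = NULL) {
  idx <- weather_index(days)
  if (is.null(sowing_year)) sowing_year <- idx$year0
  anchor <- (sowing_year - idx$year0) * 365L + as.integer(sowing_doy)
  need <- (anchor - 30L):(anchor + 149L)
  miss <- setdiff(need, idx$t)
  if (length(miss)) {
    offs <- sort(miss - anchor)
    stop("daily series does not cover sowing offsets: ",
         paste(utils::head(offs, 12L), collapse = ", "),
         if (length(offs) > 12L) " ..." else "", call. = FALSE)
  }
  if (!idx$contiguous) {
    # gaps elsewhere are tolerated as long as the season span is covered;
    # but a non-contiguous index invalidates the cumsum arithmetic, so
    # re-index the covering span only
    keep <- days_within(days, idx, need)
    idx <- weather_index(keep)
    anchor <- (sowing_year - idx$year0) * 365L + as.integer(sowing_doy)
  }
  as.data.frame(t(.features_at(idx, anchor)))
}

# Subset a daily data frame to the absolute day positions in `need`.
#' @keywords internal
days_within <- function(days, idx, need) {
  t_all <- (days$year - idx$year0) * 365L + days$doy
  days[t_all %in% need, , drop = FALSE]
}

#' Build window features for every trial
#'
#' Computes one window feature row per trial from the daily weather of
#' the trial's location, anchored at the trial's sowing day.
#'
#' @param weather Daily weather table (as from [read_daily_weather()] or
#'   [gen_daily_weather()]) covering every trial's season span.
#' @param trials Trial table with one row per trial: columns `trial_id`,
#'   `location_id`, `year`, `sowing_doy` (see [collapse_trials()]).
#' @return Data frame with `trial_id` plus the 77 feature columns.
#' @export
build_trial_features <- function(weather, trials) {
  by_loc <- split(weather, weather$location_id)
  idxs <- lapply(by_loc, weather_index)
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    loc <- as.character(trials$location_id[i])
    idx <- idxs[[loc]]
    if (is.null(idx)) stop("no weather for location ", loc, call. = FALSE)
    anchor <- (trials$year[i] - idx$year0) * 365L + as.integer(trials$sowing_doy[i])
    if (anchor - 30L < idx$t_min || anchor + 149L > idx$t_max || !idx$contiguous) {
      rows[[i]] <- aggregate_windows(by_loc[[loc]], trials$sowing_doy[i], trials$year[i])
    } else {
      rows[[i]] <- as.data.frame(t(.features_at(idx, anchor)))
    }
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(trial_id = trials$trial_id, stringsAsFactors = FALSE), out)
}
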