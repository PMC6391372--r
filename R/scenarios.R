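#' Window features under a shifted sowing date
#'
#' Re-anchors the six 30-day feature windows at `sowing_doy + shift`
#' over the same fixed observed weather; the raw weather itself is never
#' altered. `shift = 0` reproduces the unshifted feature set exactly.
#'
#' @param days Daily weather series for one location (see
#'   [aggregate_windows()]).
#' @param sowing_doy Baseline (typical) sowing day-of-year.
#' @param shift Shift in days (negative = earlier sowing).
#' @param sowing_year Calendar year of sowing.
#' @return One-row feature data frame, as from [aggregate_windows()].
#' @export
shift_features <- function(days, sowing_doy, shift, sowing_year = NULL) {
  aggregate_windows(days, sowing_doy + shift, sowing_year)
}

#' Simulate yields for a grid of sowing-date shifts
#'
#' For every state-year, builds the window features that would have been
#' observed had sowing occurred `shift` days from the state-year mean
#' (typical) sowing date, averaging features over the state-year's trial
#' locations, and predicts yield with the fitted model. The default grid
#' is -30..+30 days in 10-day increments (7 scenarios per state-year).
#'
#' @param state_years State-year table ([aggregate_state_year()]); used
#'   for the anchor sowing date, year and coordinates.
#' @param trials One-row-per-trial table giving each state-year's trial
#'   locations.
#' @param weather Daily weather table covering every shifted season.
#' @param model A fitted [fit_boost()] model (or any object with a
#'   `predict_boost()` method signature).
#' @param shifts Integer vector of shifts in days.
#' @return Data frame `state, year, shift_days, pred_yield_kg_ha` with
#'   exactly `nrow(state_years) * length(shifts)` rows; feature-build
#'   failures are collected in the `"failures"` attribute and reported,
#'   the run continues over the remaining scenarios.
#' @export
run_scenarios <- function(state_years, trials, weather, model,
                          shifts = seq(-30L, 30L, by = 10L)) {
  by_loc <- split(weather, weather$location_id)
  idxs <- lapply(by_loc, weather_index)
  locs_of <- split(as.character(trials$location_id),
                   paste(trials$state, trials$year))
  locs_of <- lapply(locs_of, unique)

  out <- vector("list", nrow(state_years) * length(shifts))
  failures <- character(0)
  featnames <- NULL
  k <- 0L
  for (i in seq_len(nrow(state_years))) {
    st <- state_years$state[i]; yr <- state_years$year[i]
    anchor <- as.integer(round(state_years$mean_sowing_doy[i]))
    locs <- locs_of[[paste(st, yr)]]
    for (s in shifts) {
      k <- k + 1L
      res <- tryCatch({
        rows <- lapply(locs, function(lc) {
          idx <- idxs[[lc]]
          a <- (yr - idx$year0) * 365L + anchor + as.integer(s)
          if (a - 30L < idx$t_min || a + 149L > idx$t_max || !idx$contiguous) {
            stop("weather coverage gap for location ", lc)
          }
          .features_at(idx, a)
        })
        fx <- Reduce(`+`, rows) / length(rows)
        fr <- as.data.frame(t(fx))
        fr$latitude <- state_years$latitude[i]
        fr$longitude <- state_years$longitude[i]
        fr$year <- yr
        pred <- predict_boost(model, fr)
        data.frame(state = st, year = yr, shift_days = s,
                   pred_yield_kg_ha = pred, stringsAsFactors = FALSE)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures <- c(failures, sprintf("%s %d shift %+d: %s", st, yr, s, res))
        out[[k]] <- data.frame(state = st, year = yr, shift_days = s,
                               pred_yield_kg_ha = NA_real_,
                               stringsAsFactors = FALSE)
      } else {
        out[[k]] <- res
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(failures)) {
    message("run_scenarios: ", length(failures), " scenario(s) failed")
  }
  attr(res, "failures") <- failures
  res
}
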