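#' Spring frost probability at emergence for a sowing shift
#'
#' For each year of a location's daily minimum-temperature history, the
#' event "spring frost" occurs if any day from crop emergence (15 days
#' after the shifted sowing date) through the spring horizon has
#' `tmin < threshold`. The probability is the fraction of event years,
#' an exact integer ratio.
#'
#' @param history Data frame `year, doy, tmin` of the location's daily
#'   minimum temperatures; every year must cover the emergence-to-horizon
#'   span.
#' @param sowing_doy Typical sowing day-of-year.
#' @param shift Sowing shift in days (negative = earlier).
#' @param threshold Frost threshold in degC (e.g. 0, -1, -2, -3).
#' @param horizon_doy Last day-of-year of the spring frost season
#'   (default 181, end of June).
#' @return List with `probability`, `n_years`, `n_events`, `emergence_doy`.
#' @export
frost_probability <- function(history, sowing_doy, shift = 0L, threshold = 0,
                              horizon_doy = 181L) {
  emergence <- sowing_doy + shift + 15L
  if (emergence > horizon_doy) {
    stop("spring horizon (doy ", horizon_doy, ") precedes emergence (doy ",
         emergence, ")", call. = FALSE)
  }
  span <- emergence:horizon_doy
  sp <- split(history, history$year)
  events <- vapply(sp, function(d) {
    sub <- d$tmin[d$doy %in% span]
    if (length(sub) != length(span)) {
      stop("history does not cover doy ", emergence, "..", horizon_doy,
           " in year ", d$year[1], call. = FALSE)
    }
    any(sub < threshold)
  }, logical(1))
  list(probability = sum(events) / length(events),
       n_years = length(events), n_events = sum(events),
       emergence_doy = as.integer(emergence))
}

#' Frost-probability profiles over shifts and thresholds
#'
#' Tabulates [frost_probability()] for every location over a grid of
#' sowing shifts and minimum-temperature thresholds.
#'
#' @param histories Data frame `location_id, year, doy, tmin` of daily
#'   minimum-temperature histories.
#' @param sowing Data frame `location_id, sowing_doy` of typical sowing
#'   dates per location.
#' @param shifts Integer vector of sowing shifts (days).
#' @param thresholds Numeric vector of frost thresholds (degC).
#' @param horizon_doy Spring horizon day-of-year.
#' @return Data frame `location_id, shift_days, threshold_c, probability,
#'   n_years`.
#' @export
frost_profiles <- function(histories, sowing,
                           shifts = c(-30L, -21L, -10L, 0L),
                           thresholds = c(0, -1, -2, -3),
                           horizon_doy = 181L) {
  by_loc <- split(histories, histories$location_id)
  grid <- expand.grid(location_id = names(by_loc), shift_days = shifts,
                      threshold_c = thresholds, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lc <- grid$location_id[i]
    sd0 <- sowing$sowing_doy[match(lc, sowing$location_id)]
    if (is.na(sd0)) stop("no sowing date for location ", lc, call. = FALSE)
    fp <- frost_probability(by_loc[[lc]], sd0, grid$shift_days[i],
                            grid$threshold_c[i], horizon_doy)
    data.frame(location_id = lc, shift_days = grid$shift_days[i],
               threshold_c = grid$threshold_c[i],
               probability = fp$probability, n_years = fp$n_years,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen locations against a frost-probability cap
#'
#' Flags locations whose frost probability exceeds the cap (default the
#' common 20% agronomic recommendation: sow only where frost probability
#' on or after emergence is below 20%), and summarizes the fraction of
#' locations exceeding the cap at each (shift, threshold).
#'
#' @param profiles A [frost_profiles()] table.
#' @param cap Probability cap (default 0.20). A probability exactly at
#'   the cap passes the screen (flagging requires `probability > cap`).
#' @return List with `verdicts` (profiles plus logical `exceeds`) and
#'   `summary` (data frame `shift_days, threshold_c, n_locations,
#'   frac_exceeding`).
#' @export
screen_locations <- function(profiles, cap = 0.20) {
  verdicts <- profiles
  verdicts$exceeds <- verdicts$probability > cap
  sp <- split(verdicts, list(verdicts$shift_days, verdicts$threshold_c),
              drop = TRUE)
  summ <- do.call(rbind, lapply(sp, function(d) {
    data.frame(shift_days = d$shift_days[1], threshold_c = d$threshold_c[1],
               n_locations = nrow(d), frac_exceeding = mean(d$exceeds),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(verdicts = verdicts,
       summary = summ[order(summ$shift_days, summ$threshold_c), , drop = FALSE])
}
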