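#' Keep the maximum-yielding maturity group of one trial
#'
#' Each trial reports mean yield for several maturity groups (MG); the
#' analysis keeps the MG with the maximum yield, under the assumption
#' that the year's weather favored that earliness class. Ties are broken
#' by the alphabetically earliest MG label.
#'
#' @param mg_yields Named numeric vector, MG label -> mean yield (kg/ha).
#' @return List with `yield` (kg/ha) and `mg` (winning label).
#' @export
select_max_yield_mg <- function(mg_yields) {
  if (!is.numeric(mg_yields) || length(mg_yields) == 0 || is.null(names(mg_yields))) {
    stop("mg_yields must be a non-empty named numeric vector", call. = FALSE)
  }
  o <- order(names(mg_yields))
  mg_yields <- mg_yields[o]
  i <- which.max(mg_yields)  # first max in label order
  list(yield = unname(mg_yields[i]), mg = names(mg_yields)[i])
}

#' Collapse a long trial table to one row per trial
#'
#' Applies [select_max_yield_mg()] within each trial of a long-format
#' trial table (one row per MG).
#'
#' @param trials_long Data frame as returned by [read_trials()].
#' @return Data frame with one row per `trial_id`: `trial_id, state,
#'   year, location_id, sowing_doy, mg, yield_kg_ha`.
#' @export
collapse_trials <- function(trials_long) {
  sp <- split(trials_long, trials_long$trial_id)
  rows <- lapply(sp, function(d) {
    best <- select_max_yield_mg(stats::setNames(d$yield_kg_ha, d$mg))
    data.frame(trial_id = d$trial_id[1], state = d$state[1], year = d$year[1],
               location_id = d$location_id[1], sowing_doy = d$sowing_doy[1],
               mg = best$mg, yield_kg_ha = best$yield, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$state, out$year, out$trial_id), , drop = FALSE]
}

#' Interpolate the 50%-sown date from weekly crop-progress points
#'
#' Linear interpolation between the two adjacent weekly reports that
#' bracket 50% of hectares sown; the result is rounded half-up to the
#' nearest integer day-of-year. A report exactly at 50% returns its own
#' day. The series must be non-decreasing and must reach 50%.
#'
#' @param doy Day-of-year of each weekly report (increasing).
#' @param pct_sown Cumulative percent of hectares sown (0..100).
#' @return Integer day-of-year at which 50% of hectares were sown.
#' @examples
#' interpolate_50pct_sown(c(130, 137), c(40, 60))  # 134
#' @export
interpolate_50pct_sown <- function(doy, pct_sown) {
  if (length(doy) != length(pct_sown) || length(doy) < 1) {
    stop("doy and pct_sown must be equal-length, non-empty", call. = FALSE)
  }
  o <- order(doy)
  doy <- doy[o]; pct_sown <- pct_sown[o]
  if (any(diff(pct_sown) < 0)) {
    stop("pct_sown must be non-decreasing over time", call. = FALSE)
  }
  exact <- which(pct_sown == 50)
  if (length(exact)) return(as.integer(doy[exact[1]]))
  if (max(pct_sown) < 50) stop("series never reaches 50% sown", call. = FALSE)
  if (pct_sown[1] > 50) stop("series starts above 50% sown; cannot bracket", call. = FALSE)
  i <- which(pct_sown > 50)[1]
  d0 <- doy[i - 1]; d1 <- doy[i]
  p0 <- pct_sown[i - 1]; p1 <- pct_sown[i]
  x <- d0 + (50 - p0) / (p1 - p0) * (d1 - d0)
  as.integer(floor(x + 0.5))  # round half-up
}

#' Average trials to the state-year analysis set
#'
#' Unweighted means of yield and of every window-feature column within
#' each (state, year); also records the number of trials and the mean
#' sowing day. This is the analysis unit for the tree and the boosting
#' model: one row per state-year.
#'
#' @param trials One-row-per-trial table ([collapse_trials()]).
#' @param features Per-trial feature table ([build_trial_features()]).
#' @param coords Optional data frame `state, latitude, longitude` of
#'   state reference coordinates; when omitted, trial coordinates are
#'   unavailable and the columns are filled with NA.
#' @return Data frame with one row per state-year: `state, year,
#'   n_trials, mean_sowing_doy, yield`, latitude/longitude, and the mean
#'   of each feature column.
#' @export
aggregate_state_year <- function(trials, features, coords = NULL) {
  stopifnot(all(trials$trial_id %in% features$trial_id))
  m <- merge(trials, features, by = "trial_id")
  featcols <- setdiff(names(features), "trial_id")
  sp <- split(m, list(m$state, m$year), drop = TRUE)
  rows <- lapply(sp, function(d) {
    base <- data.frame(state = d$state[1], year = d$year[1],
                       n_trials = nrow(d),
                       mean_sowing_doy = mean(d$sowing_doy),
                       yield = mean(d$yield_kg_ha),
                       stringsAsFactors = FALSE)
    cbind(base, as.data.frame(as.list(colMeans(d[, featcols, drop = FALSE]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(coords)) {
    out <- merge(out, coords[, c("state", "latitude", "longitude")],
                 by = "state", all.x = TRUE)
  } else {
    out$latitude <- NA_real_; out$longitude <- NA_real_
  }
  out[order(out$state, out$year), , drop = FALSE]
}
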