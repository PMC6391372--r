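#' Production change implied by a yield change
#'
#' Applies a fractional yield change to a state-year's non-irrigated
#' production.
#'
#' @param frac_yield_change Fractional yield change (e.g. 0.05 for +5%).
#' @param production_t Production in metric tonnes (> 0).
#' @return List with `fraction` (echoed) and `tonnes` (change in t).
#' @export
production_change <- function(frac_yield_change, production_t) {
  if (any(production_t < 0)) stop("production must be non-negative", call. = FALSE)
  list(fraction = frac_yield_change, tonnes = frac_yield_change * production_t)
}

#' Adjust a nominal income to 2016 US$
#'
#' @param income_usd Nominal income in US$.
#' @param year Calendar year of the income.
#' @param cpi CPI table with columns `year, deflator_to_2016`
#'   (deflator(2016) = 1).
#' @return Income in 2016 US$.
#' @export
inflation_adjust <- function(income_usd, year, cpi) {
  i <- match(year, cpi$year)
  if (anyNA(i)) {
    stop("no CPI deflator for year(s): ",
         paste(unique(year[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  income_usd * cpi$deflator_to_2016[i]
}

#' Cumulative inflation-adjusted monetary gain per state
#'
#' Three-step monetary effect of optimal sowing: the state's fractional
#' yield (hence production) change is applied to each year's
#' inflation-adjusted total income and summed over the period:
#' `cumulative = sum_years income_2016 * frac_change`.
#'
#' @param econ Economics table `state, year, income_usd, production_t,
#'   hectares` covering every (state, year) implied by `changes`.
#' @param cpi CPI table `year, deflator_to_2016`.
#' @param changes Data frame `state, frac_yield_change` (one row per
#'   state; the fraction applies to all years of that state).
#' @return Data frame, one row per state: `state, frac_yield_change,
#'   cum_gain_usd2016, mean_hectares, n_years`.
#' @export
cumulative_gain <- function(econ, cpi, changes) {
  stopifnot(all(c("state", "frac_yield_change") %in% names(changes)))
  miss <- setdiff(changes$state, econ$state)
  if (length(miss)) {
    stop("economics table has no rows for state(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(changes)), function(i) {
    st <- changes$state[i]
    frac <- changes$frac_yield_change[i]
    e <- econ[econ$state == st, , drop = FALSE]
    inc16 <- inflation_adjust(e$income_usd, e$year, cpi)
    data.frame(state = st, frac_yield_change = frac,
               cum_gain_usd2016 = sum(inc16 * frac),
               mean_hectares = mean(e$hectares),
               n_years = nrow(e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-hectare monetary effect
#'
#' Converts a cumulative monetary gain into US$/ha. The default
#' convention divides by hectare-years (mean hectares times the number
#' of years, an annualized per-hectare effect); the alternative divides
#' by mean hectares only (a cumulative per-hectare effect).
#'
#' @param cum_gain_usd2016 Cumulative gain in 2016 US$.
#' @param mean_hectares 10-year (or period) mean hectares (> 0).
#' @param n_years Number of years in the cumulative period.
#' @param convention `"hectare_years"` (default) or `"hectares"`.
#' @return Gain in 2016 US$/ha.
#' @export
per_hectare <- function(cum_gain_usd2016, mean_hectares, n_years,
                        convention = c("hectare_years", "hectares")) {
  convention <- match.arg(convention)
  if (any(mean_hectares <= 0)) stop("hectares must be positive", call. = FALSE)
  denom <- if (convention == "hectare_years") mean_hectares * n_years else mean_hectares
  cum_gain_usd2016 / denom
}

#' Full monetary-effect table and national roll-up
#'
#' Convenience wrapper: per-state cumulative 2016-US$ gains from the
#' response curves' fractional yield changes, per-hectare effects, and
#' the exact national total (sum over states).
#'
#' @param curves A [fit_response()] result (uses `pct_gain`).
#' @param econ,cpi Tables as in [cumulative_gain()].
#' @param convention Per-hectare convention, see [per_hectare()].
#' @return List with `by_state` (data frame: state, frac_yield_change,
#'   cum_gain_usd2016, per_ha_usd2016) and `national` (list with
#'   `cum_gain_usd2016`).
#' @export
compute_economics <- function(curves, econ, cpi,
                              convention = c("hectare_years", "hectares")) {
  convention <- match.arg(convention)
  changes <- data.frame(state = curves$state,
                        frac_yield_change = curves$pct_gain,
                        stringsAsFactors = FALSE)
  by_state <- cumulative_gain(econ, cpi, changes)
  by_state$per_ha_usd2016 <- per_hectare(by_state$cum_gain_usd2016,
                                         by_state$mean_hectares,
                                         by_state$n_years, convention)
  list(by_state = by_state,
       national = list(cum_gain_usd2016 = sum(by_state$cum_gain_usd2016)))
}
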