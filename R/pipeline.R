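#' Run the full sowing-shift analysis pipeline
#'
#' Executes every stage on already-loaded inputs: maturity-group
#' pooling, per-trial window features, state-year averaging, the
#' conditional-inference tree, the boosting model with a stratified
#' train/test evaluation, the sowing-shift scenario grid, the quadratic
#' response optima, the national summary, the monetary effects, and the
#' frost screen.
#'
#' @param trials_long Long trial table (reader schema, one row per MG).
#' @param weather Daily weather table covering all shifted seasons.
#' @param econ,cpi Economics and CPI tables.
#' @param frost_histories,frost_sowing Frost inputs (may be `NULL` to
#'   skip the frost stage).
#' @param coords Optional `state, latitude, longitude` reference table.
#' @param tree_controls A [citree_controls()].
#' @param boost_ctl A [boost_controls()]. The pipeline default uses
#'   component-wise linear base learners: the counterfactual stage must
#'   extrapolate feature values beyond each state's observed range, and
#'   linear base functions transport there, while piecewise-constant
#'   stumps saturate at the training hull.
#' @param boost_level Fit the predictive model on `"trial"` records
#'   (default; about five times the records of the state-year set) or on
#'   the aggregated `"state_year"` records. Scenario predictions are
#'   always made at the state-year level.
#' @param shifts Scenario shift grid (days).
#' @param response_method Passed to [fit_response()].
#' @param frost_shifts,frost_thresholds Frost screening grid.
#' @return List with every stage's outputs: `state_years`, `tree`,
#'   `vpd_slope`, `split_info`, `model`, `fit_eval`, `scenarios`,
#'   `curves`, `national`, `economics`, `frost`.
#' @export
run_pipeline <- function(trials_long, weather, econ, cpi,
                         frost_histories = NULL, frost_sowing = NULL,
                         coords = NULL,
                         tree_controls = citree_controls(),
                         boost_ctl = boost_controls(
                           base_learner = "componentwise_linear"),
                         boost_level = c("trial", "state_year"),
                         shifts = seq(-30L, 30L, by = 10L),
                         response_method = "lmm",
                         frost_shifts = c(-30L, -21L, -10L, 0L),
                         frost_thresholds = c(0, -1, -2, -3)) {
  boost_level <- match.arg(boost_level)
  trials <- collapse_trials(trials_long)
  features <- build_trial_features(weather, trials)
  sy <- aggregate_state_year(trials, features, coords = coords)

  # interpretation tree on the 31 candidate predictors
  tp <- tree_predictor_names()
  Xtree <- sy[, setdiff(tp, "state"), drop = FALSE]
  Xtree$state <- factor(sy$state)
  tree <- fit_citree(Xtree, sy$yield, tree_controls)
  root <- tree$nodes[tree$nodes$id == 1L, ]
  vpd_slope <- tryCatch(node_vpd_slope(sy, "vpd_mean_W3"), error = function(e) NULL)

  # predictive boosting model: evaluate on a held-out stratified split,
  # then refit on all records for the counterfactual stage
  bp <- boost_predictor_names()
  if (boost_level == "trial") {
    tf <- merge(trials, features, by = "trial_id")
    wl <- unique(weather[, c("location_id", "latitude", "longitude")])
    tf$latitude <- wl$latitude[match(tf$location_id, wl$location_id)]
    tf$longitude <- wl$longitude[match(tf$location_id, wl$location_id)]
    Xb <- tf[, bp, drop = FALSE]
    yb <- tf$yield_kg_ha
    idx <- stratified_split(tf, boost_ctl$train_frac,
                            strata = c("state", "year"), seed = boost_ctl$seed)
  } else {
    Xb <- sy[, bp, drop = FALSE]
    yb <- sy$yield
    # one record per (state, year) cell, so the finest non-degenerate
    # stratum for the 85/15 partition is the year
    idx <- stratified_split(sy, boost_ctl$train_frac, strata = "year",
                            seed = boost_ctl$seed)
  }
  model_val <- fit_boost(Xb[idx$train, , drop = FALSE], yb[idx$train], boost_ctl)
  fit_eval <- evaluate_boost(model_val, Xb[idx$test, , drop = FALSE], yb[idx$test])
  model <- fit_boost(Xb, yb, boost_ctl)

  # counterfactual scenarios and response optima
  scen <- run_scenarios(sy, trials, weather, model, shifts = shifts)
  curves <- fit_response(scen, method = response_method,
                         shift_range = range(shifts))
  weights <- stats::aggregate(production_t ~ state, data = econ, FUN = mean)
  names(weights)[2] <- "weight"
  national <- national_summary(curves, weights)
  economics <- compute_economics(curves, econ, cpi)

  frost <- NULL
  if (!is.null(frost_histories)) {
    prof <- frost_profiles(frost_histories, frost_sowing,
                           shifts = frost_shifts, thresholds = frost_thresholds)
    frost <- screen_locations(prof)
  }

  list(state_years = sy, tree = tree,
       split_info = list(variable = root$split_var, threshold = root$threshold,
                         p_adjusted = root$p_adjusted),
       vpd_slope = vpd_slope, model = model, fit_eval = fit_eval,
       scenarios = scen, curves = curves, national = national,
       economics = economics, frost = frost)
}
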