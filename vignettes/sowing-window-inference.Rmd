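---
title: "Weather-window inference for optimal soybean sowing dates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weather-window inference for optimal soybean sowing dates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rainfed soybean yield in the United States is constrained by in-season
weather, most sharply by atmospheric water demand (vapor pressure
deficit, Vpd) during mid-summer reproductive growth. Because the crop's
sensitivity changes with its developmental stage, and because the stage
calendar is set by the sowing date, shifting sowing earlier or later
moves the sensitive stages across the seasonal weather pattern. This
package implements a complete inference chain for that problem: identify
*which* 30-day developmental windows carry yield-limiting weather
signals, build a predictive yield model from window-aggregated weather,
simulate yields under counterfactual sowing dates over the same observed
weather, extract state-specific optimal sowing shifts from the simulated
response, and translate the yield changes into inflation-adjusted
monetary effects and spring-frost risk.

All stages operate on plain tabular inputs (daily weather per
location-year, trial yields by maturity group, weekly crop-progress
reports, state income/production tables, a CPI deflator series), so the
pipeline runs identically on user-supplied data or on the package's own
synthetic study.

## Derived weather variables

Daily saturation vapor pressure uses a Tetens-type curve,

$$ e_s(T) = 0.6107 \exp\!\left(\frac{17.269\,T}{237.3 + T}\right) \quad
   [\mathrm{kPa},\ T\ \mathrm{in}\ ^\circ\mathrm{C}], $$

and daily Vpd is defined operationally as $e_s(T_{max}) - e_s(T_{min})$:
the daily minimum temperature stands in for the dew point, so the
difference measures how far the day's peak atmospheric demand sits above
the moisture the airmass held at dawn. This is a deliberate,
field-standard simplification (a dew-point-based Vpd is *not* offered).
Relative humidity is the actual vapor pressure divided by the mean of
$e_s(T_{max})$ and $e_s(T_{min})$; values above 1 are passed through with
a message because gridded weather products occasionally produce them.

## Sowing-relative windows and the feature sets

The season is cut into six 30-day windows anchored on the sowing day:
`Wpre` (30 days before sowing up to the day before), `W1` (sowing day
through 29 days after), and `W2`-`W5` continuing to 149 days after
sowing. Bins are half-open; the sowing day belongs to `W1`. Within each
window (and season-wide over the whole -30..149 span) the pipeline
accumulates precipitation and solar radiation, averages daily Vpd,
maximum temperature and relative humidity, and counts wet days
(precipitation > 1 mm, "a") and dry days (< 1 mm, "b") with their ratio
a/b. A day of exactly 1 mm falls in neither count, matching the strict
inequalities of the definitions. When b = 0 the ratio is reported as
a/(b+1) with a companion flag column, which avoids infinities while
preserving the ordering; the flag travels in the output schema but is
never a model feature.

Two feature sets are drawn from this pool:

* the **tree set** - cumulative precipitation, cumulative radiation,
  mean Vpd, mean maximum temperature and mean relative humidity over the
  six windows, plus the categorical state: exactly 31 candidate
  predictors. Daily minimum temperature and day length are computed and
  stored but excluded, because they confound with the retained
  variables and the tree exists for interpretation;
* the **model set** - the five tree variables plus a, b and a/b over
  all windows and the season, with latitude, longitude and calendar
  year. Year absorbs the technology trend, which would otherwise bias
  the weather coefficients. Minimum temperature and day length stay
  excluded here too; day length in particular is a deterministic
  function of latitude and date, so it carries no identifiable signal in
  trial data yet would move strongly under counterfactual sowing shifts
  - any weight it absorbed as a latitude proxy would corrupt the
  scenario stage.

Solar radiation is summed as the plain daily column; no day-length
energy integration is attempted (gridded products report a daylight
average, and the choice is documented rather than hidden).

## Trial preparation

Trials report several maturity groups; the analysis keeps the group with
the maximum yield, on the premise that the year's weather favored that
earliness class (ties break to the alphabetically earliest label). One
feature row is built per trial at the trial's own sowing date, and
yields and features are then averaged, unweighted, within state x year.
The weekly crop-progress reports give an interpolated 50%-sown date per
state-year (linear between the bracketing weekly points, rounded
half-up); this is a diagnostic of how the trial program brackets farmer
practice - the analysis itself is anchored on trial sowing dates.

## The conditional-inference tree

Variable selection and stopping use permutation tests rather than
exhaustive split-quality search, which keeps variable selection unbiased
across predictors with different numbers of potential cut points. At
each node the association of every candidate with yield is measured by a
Monte-Carlo permutation p-value of a linear statistic - the absolute
centered cross-product for numeric predictors, the between-group sum of
squares for the state factor. P-values are Bonferroni-multiplied by the
number of candidates (31); if the smallest adjusted p-value exceeds
alpha = 0.05 the node stops. Otherwise the winning variable is split at
the cut maximizing the between-group sum of squares, subject to both
sides holding at least `min_terminal` observations; numeric thresholds
are reported at the midpoint of the adjacent observed values, and state
splits search binary partitions along the ordering of state mean yields,
which is exact for a least-squares criterion. Defaults: more than 37
observations to attempt a split, more than 18 per leaf, depth at most
10. The reference framework's asymptotic quadratic-form test would be an
acceptable alternative to Monte-Carlo permutation; the permutation route
was chosen because it is assumption-free and exactly reproducible under
a seed. Note that the Bonferroni cap makes the smallest achievable
adjusted p-value `31/(n_perm+1)`, so `n_perm` must comfortably exceed
`31/alpha` (the 9999 default does; a few hundred would never split).

Within tree-defined strata, `node_vpd_slope()` regresses yield on a
named window feature. With two or more states present the model includes
state intercepts, so the reported slope is the common within-state
slope; a pooled slope without intercepts would be attenuated toward zero
by between-state differences in the feature's climatological level.
Slope homogeneity across states is assessed by the state-by-feature
interaction F-test.

## The boosting model

The predictive model is functional gradient descent under squared-error
loss: starting from the training mean, each iteration fits every
candidate base learner to the current residuals, keeps the one with the
largest residual sum-of-squares reduction, and adds 0.2 times its fitted
function. The iteration count (600) and step length (0.2) are fixed;
there is no internal early stopping. Two base learners are provided:
regression stumps and component-wise simple linear regressions. The
pipeline default is the linear learner, for a reason that matters to the
science: the counterfactual stage must evaluate the model at feature
values beyond each state's observed range (a 30-day sowing shift moves
window features along the seasonal gradient), and linear base functions
extrapolate there, while stumps are piecewise constant and saturate at
the training hull, flattening the simulated response curves exactly
where the optimum is decided. In the boosted limit the component-wise
linear model approaches the least-squares fit on all features, which is
the correctly specified estimator for the synthetic study's additive
truth.

The model is fitted on trial-level records. The real-data argument for
state-level fitting is the known inaccuracy of gridded weather at trial
resolution; that mismatch does not exist here, and the roughly fivefold
larger sample materially stabilizes the attribution of effects across
the strongly collinear window features (within a window, Vpd, maximum
temperature and relative humidity co-move; precipitation, wet days and
the a/b ratio co-move). Evaluation uses an 85/15 split stratified by
state within year - at trial level every stratum holds several records,
so the stratification is meaningful - and the deployed model is then
refit on all records, the standard validate-then-refit sequence.

## Counterfactual scenarios and the response optimum

Seven scenario datasets are built per state-year by re-anchoring the
feature windows at the state-year mean sowing date plus -30, -20, -10,
0, +10, +20, +30 days, over the same fixed observed weather; features
are averaged across the state-year's trial locations and predicted with
the fitted model, giving (number of state-years) x 7 simulated yields.
Nothing about the weather itself is resampled - the counterfactual is
purely "the same season, entered earlier or later".

The simulated yields are fitted by a hierarchical quadratic: per-state
fixed intercepts and linear/quadratic shift terms, with random
intercepts for year and for state-within-year (the residual absorbs the
shift-within-state-within-year level on this balanced grid). A
documented two-stage fallback (per state-year quadratics pooled by
precision weighting) covers degenerate inputs such as a single year.
Each state's optimum is the vertex -b/(2c) clipped to the simulated
range; convex fits take the better grid endpoint and are flagged. The
gain is the fitted yield at the optimum minus at shift zero, which is
non-negative by construction. The national summary production-weights
the per-state optima and percentage gains, excluding later-is-better
states (configurable); an unweighted variant is available.

## Economics and frost screening

The monetary chain is deliberately elementary: the state's fractional
yield change at its optimum is applied to each year's income, incomes
are deflated to 2016 US$ by the supplied CPI series, and the products
are summed over the decade. Gains are exactly additive over states and
years and homogeneous of degree one in income - properties the test
suite asserts literally. The per-hectare effect divides the cumulative
gain by hectare-years (mean hectares x number of years) by default; the
divide-by-hectares-once convention is selectable because the choice is
genuinely ambiguous in common reporting.

Frost risk is a pure counting exercise over multi-decade daily-minimum
histories: for a candidate shift, emergence is 15 days after the shifted
sowing date, and a year counts as a frost year if any day from emergence
through the spring horizon (day-of-year 181 by default) drops below the
threshold (0, -1, -2, -3 degC). The probability is the exact integer
ratio of frost years; events nest, so probabilities are monotone in both
threshold and shift. Locations are screened against the 20% agronomic
recommendation; a probability exactly at the cap passes. The event is
"any day on or after emergence", the reading consistent with the
recommendation's phrasing; emergence-day-only is the natural alternative
and would only lower probabilities.

## The synthetic study and its ground truth

The generator emulates the full study design - 27 states (realistic
coordinates and production weights), 10 years, 5 trial locations per
state sowing on a staggered schedule spanning about six weeks around the
state's typical date, three maturity groups per trial, 46-year frost
climatologies, state economics at a headline scale of about nine billion
2016 US$ - with every planted effect injected *through the same window
features the pipeline computes*, so recovery failures localize to the
inference stages rather than the generator.

Daily weather per location follows a deterministic seasonal skeleton
plus noise: an annual temperature sinusoid with a calibrated steep
early-summer rise (the Vpd onset, via a tanh ramp in both the level and
the diurnal range), a two-regime precipitation seasonality (wet-day
probability and intensity step up at a calibrated onset, then decline
into a late-summer dry-down), vapor pressure from a fluctuating
dew-point depression, AR(1) daily noise, and - importantly - a common
inter-annual anomaly that moves both seasonal onsets together from year
to year. That anomaly is the dominant real source of year-to-year
contrast at a fixed site, and it is also precisely the direction a
sowing shift traverses, so it is what lets a regression model learn the
transportable response.

Trial yield is a baseline (with a latitudinal tilt, learnable through
the latitude feature) plus a 30 kg/ha/year technology trend plus three
window effects at the scales reported for this system: -1135 kg/ha per
kPa of W3 (61-90 days after sowing) mean Vpd, -350 kg/ha/kPa of
pre-sowing Vpd, and +7 kg/ha per mm of W3 precipitation, with Gaussian
state (100), state-year (120) and trial (250 kg/ha) noise. Because the
effects act on raw features, hot high-Vpd states yield less - the
between-state gradient is the honest consequence of climate, exactly
representable by an additive model, rather than an arbitrary state
intercept no feature could explain.

The ground truth is recorded before any pipeline stage runs. For each
state, the expected response over the shift grid is computed from the
seasonal skeleton with two Gauss-Hermite quadratures: over the
inter-annual onset anomaly, and over the daily temperature noise inside
the saturation-vapor-pressure curve (es is convex, so the expected Vpd
of noisy weather is not the Vpd of the noise-free curve - ignoring this
biases the truth by several days for some states). The per-state
seasonal onsets are calibrated by deterministic grid search so that the
vertex of the least-squares quadratic through the 7-point expected
response lands on the state's target optimum, with concavity required.
Defining the planted optimum as that quadratic vertex - the same
estimand the pipeline extracts - keeps truth and estimate on a common
scale for tent-shaped responses that are only locally quadratic.

Targets average -12 days production-weighted across the
earlier-is-better states, with Texas and Mississippi planted as the two
later-is-better states and per-state gains spanning roughly 40-650
kg/ha (about 1-25% of the state's expected yield; weighted nationally,
about 4%). A note on scale honesty: with the -1135 kg/ha/kPa Vpd slope
and physically plausible seasonal steepness, a production-weighted
national gain anywhere near 10% at a -12-day mean optimum is not
constructible through weather-mediated responses - it would require
yield losses of order 100 kg/ha per day of delayed sowing in the major
producing states. The generator therefore plants per-state gains on the
reported tens-to-hundreds-of-kg/ha scale and accepts the ~4% weighted
national gain that implies.

## What the recovery tests can and cannot show

The test suite closes the loop: generate, run the pipeline, compare to
the recorded truth. The national quantities - production-weighted mean
optimal shift, weighted percentage gain, the W3 Vpd slope with its
confidence interval, the cumulative monetary total - recover reliably
across seeds. The per-state optima mostly recover within +-3 days, but
not for 90%+ of states, and the limit is informative: even with the
*true* generating coefficients substituted for the fitted model, only
about 70-80% of state optima land within +-3 days, because the
counterfactual stage re-uses a single 10-year weather realization and
the vertex of a sharp tent-shaped response is sensitive to the tail
scenario points, which average over only 50 location-years. The
per-state precision of this design is therefore about +-4-5 days for
the sharpest southern responses, and no estimator can beat it without
more years, more locations, or external weather replication. The yield
noise levels, by contrast, barely matter for this floor (they are
constant across shifts within a state-year and are absorbed by the
response model's random effects).

The generator emulates seasonal structure, regime changes, inter-annual
anomalies and realistic noise, but not spatial correlation of weather
across locations, storm tracks, soil heterogeneity, or measurement
artifacts of gridded weather products. Passing recovery tests on it
therefore demonstrates that the inference machinery is correct and
statistically calibrated at the study's scale - not that real-data
conclusions are automatic, since real data add exactly the complications
the generator omits (and the trial-level fitting choice, in particular,
would need to be revisited against gridded-weather error).

## Numerical and procedural choices worth knowing

* Window aggregation uses cumulative-sum indexing over contiguous daily
  series (an O(1) window query); a brute-force day-loop oracle in the
  tests pins it to 1e-10. Leap days are dropped on read so every year
  has 365 slots; series may span calendar year boundaries.
* Missing weather days are rejected, never imputed; the reader reports
  the offending location-years, and the window builder lists the missing
  sowing offsets.
* Permutation p-values are `(1 + #{perm >= obs}) / (n_perm + 1)`, valid
  at any `n_perm`; ties in the statistic are resolved conservatively
  with a relative tolerance. Selection ties break by column order;
  equal-split ties by the first maximizing cut.
* The stratified split rounds the training count to the nearest integer
  per stratum and sends singleton strata to training with a message.
* The scenario stage collects per-row failures (e.g. a coverage gap for
  one location) and continues, reporting the failed rows in an
  attribute; the response fit drops missing predictions.
* `sim_config()` exposes every generator default (scale, coefficients,
  noise levels, economics target); all randomness descends from a
  single integer seed, and generator functions restore the caller's RNG
  state.
* Problem sizes in the shipped tests: the full 27x10x5 study for the
  end-to-end checks (about a minute), a 3x3x3 study for module-level
  properties, 100-series window oracles, 1000-replicate test-size
  calibration, and 20-replicate tree-structure recovery.
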