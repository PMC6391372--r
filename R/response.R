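#' Fit the quadratic sowing-date response and extract per-state optima
#'
#' Models simulated yield as a state-specific quadratic in the sowing
#' shift. The default `"lmm"` route fits a single hierarchical linear
#' mixed model with per-state fixed intercepts, linear and quadratic
#' shift terms, and random intercepts for year and state-within-year
#' (the shift-within-state-within-year level is absorbed by the residual
#' on this balanced grid). The `"two_stage"` route fits an ordinary
#' quadratic per state-year and pools coefficients within state by
#' precision-weighted averaging; it is also the automatic fallback when
#' the mixed model cannot be fitted (e.g. a single year of data).
#'
#' The optimum shift is the vertex `-b/(2c)` of the state's quadratic,
#' clipped to the simulated shift range; convex fits (`c >= 0`) take the
#' best grid endpoint and are flagged. The gain is the fitted yield at
#' the optimum minus at shift 0, which is non-negative by construction.
#'
#' @param scenarios Scenario table from [run_scenarios()] (`state`,
#'   `year`, `shift_days`, `pred_yield_kg_ha`); rows with missing
#'   predictions are dropped.
#' @param method `"lmm"` or `"two_stage"`.
#' @param shift_range Length-2 clipping range for the optimum (days).
#' @return Data frame of class `response_curves`, one row per state:
#'   intercept (kg/ha at shift 0), linear (kg/ha/day) and quadratic
#'   (kg/ha/day^2) coefficients, `opt_shift` (days), `gain_kg_ha`,
#'   `pct_gain` (fraction of the shift-0 yield), and the `convex` and
#'   `clipped` flags. Variance components (lmm route) are attached as
#'   the `"varcomp"` attribute.
#' @export
fit_response <- function(scenarios, method = c("lmm", "two_stage"),
                         shift_range = c(-30, 30)) {
  method <- match.arg(method)
  d <- scenarios[!is.na(scenarios$pred_yield_kg_ha), , drop = FALSE]
  if (length(unique(d$shift_days)) < 3) {
    stop("need at least 3 distinct shifts", call. = FALSE)
  }
  d$state <- factor(d$state)
  d$shift <- d$shift_days
  d$shift2 <- d$shift_days^2
  varcomp <- NULL
  coefs <- NULL

  if (method == "lmm" && length(unique(d$year)) >= 2 && nlevels(d$state) >= 1) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(pred_yield_kg_ha ~ 0 + state + state:shift + state:shift2 +
                     (1 | year) + (1 | year:state),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      )),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fe <- lme4::fixef(fit)
      sts <- levels(d$state)
      coefs <- data.frame(
        state = sts,
        intercept = fe[paste0("state", sts)],
        linear = fe[paste0("state", sts, ":shift")],
        quadratic = fe[paste0("state", sts, ":shift2")],
        stringsAsFactors = FALSE)
      vc <- as.data.frame(lme4::VarCorr(fit))
      varcomp <- stats::setNames(vc$vcov, vc$grp)
    }
  }
  if (is.null(coefs)) {
    # two-stage: per state-year OLS quadratics, precision-weighted pooling
    sp <- split(d, list(d$state, d$year), drop = TRUE)
    per_sy <- lapply(sp, function(g) {
      f <- stats::lm(pred_yield_kg_ha ~ shift + shift2, data = g)
      se2 <- suppressWarnings(diag(stats::vcov(f)))  # 0 on noiseless fits
      list(state = as.character(g$state[1]), b = stats::coef(f), se2 = se2)
    })
    states <- sort(unique(vapply(per_sy, `[[`, character(1), "state")))
    coefs <- do.call(rbind, lapply(states, function(s) {
      fits <- Filter(function(z) z$state == s, per_sy)
      B <- do.call(rbind, lapply(fits, `[[`, "b"))
      V <- do.call(rbind, lapply(fits, `[[`, "se2"))
      w <- 1 / pmax(V, 1e-12)
      if (any(!is.finite(w))) w[] <- 1
      bw <- colSums(B * w) / colSums(w)
      data.frame(state = s, intercept = bw[1], linear = bw[2],
                 quadratic = bw[3], stringsAsFactors = FALSE)
    }))
  }
  rownames(coefs) <- NULL

  qval <- function(b, c2, s) b * s + c2 * s^2  # yield relative to shift 0
  lo <- shift_range[1]; hi <- shift_range[2]
  opt <- numeric(nrow(coefs)); convex <- logical(nrow(coefs))
  clipped <- logical(nrow(coefs))
  for (i in seq_len(nrow(coefs))) {
    b <- coefs$linear[i]; c2 <- coefs$quadratic[i]
    if (c2 < 0) {
      v <- -b / (2 * c2)
      clipped[i] <- v < lo || v > hi
      opt[i] <- min(max(v, lo), hi)
    } else {
      convex[i] <- TRUE
      opt[i] <- if (qval(b, c2, lo) >= qval(b, c2, hi)) lo else hi
    }
  }
  gain <- qval(coefs$linear, coefs$quadratic, opt)
  out <- data.frame(coefs, opt_shift = opt, gain_kg_ha = gain,
                    pct_gain = gain / coefs$intercept,
                    convex = convex, clipped = clipped,
                    stringsAsFactors = FALSE)
  attr(out, "varcomp") <- varcomp
  attr(out, "method") <- if (is.null(varcomp)) "two_stage" else "lmm"
  class(out) <- c("response_curves", class(out))
  out
}

#' National summary of optimal sowing shifts
#'
#' Production-weighted mean of the per-state optimal shifts and
#' production-weighted total yield change at the optima. States with a
#' positive (later-than-typical) optimum are excluded from the mean
#' shift by default, mirroring the convention of summarizing the
#' earlier-sowing signal separately from the few states where later
#' sowing helps; the exclusion list is configurable.
#'
#' @param curves A [fit_response()] result.
#' @param weights Data frame `state, weight` (e.g. mean production in
#'   tonnes); every state in `curves` must have a weight.
#' @param exclude Character vector of states to exclude (in addition to
#'   positive-optimum states when `exclude_positive`).
#' @param exclude_positive Exclude states whose optimum is > 0 days?
#' @param weighted Production-weighted (default) or unweighted summary.
#' @return List with `mean_shift_days`, `total_yield_change_pct`
#'   (percent), `excluded` (states left out), and `n_states`.
#' @export
national_summary <- function(curves, weights, exclude = character(0),
                             exclude_positive = TRUE, weighted = TRUE) {
  stopifnot(all(c("state", "weight") %in% names(weights)))
  miss <- setdiff(curves$state, weights$state)
  if (length(miss)) {
    stop("missing weight for state(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  w <- weights$weight[match(curves$state, weights$state)]
  if (!weighted) w <- rep(1, length(w))
  drop <- curves$state %in% exclude
  if (exclude_positive) drop <- drop | curves$opt_shift > 0
  keep <- !drop
  if (!any(keep)) stop("no states left after exclusions", call. = FALSE)
  list(
    mean_shift_days = sum(curves$opt_shift[keep] * w[keep]) / sum(w[keep]),
    total_yield_change_pct = 100 * sum(curves$pct_gain[keep] * w[keep]) / sum(w[keep]),
    excluded = curves$state[drop],
    n_states = sum(keep)
  )
}
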