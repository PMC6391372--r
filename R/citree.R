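#' Controls for the conditional-inference regression tree
#'
#' Defaults follow the screening design used for the yield analysis:
#' Bonferroni-adjusted permutation tests at alpha = 0.05, intermediate
#' nodes of more than 37 observations, terminal nodes of more than 18
#' observations, and a maximum depth of 10 levels.
#'
#' @param alpha Significance level for the (adjusted) association test.
#' @param bonferroni Multiply p-values by the number of candidate
#'   predictors at the node (capped at 1)?
#' @param min_internal Minimum observations for a node to attempt a split.
#' @param min_terminal Minimum observations in any leaf.
#' @param max_depth Maximum tree depth (root = depth 1).
#' @param n_perm Monte-Carlo permutations for the association test.
#' @param seed Integer seed making the permutation tests reproducible.
#' @return List of class `citree_controls`.
#' @export
citree_controls <- function(alpha = 0.05, bonferroni = TRUE, min_internal = 38L,
                            min_terminal = 19L, max_depth = 10L,
                            n_perm = 9999L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, min_terminal <= min_internal,
            max_depth >= 1, n_perm >= 1)
  structure(list(alpha = alpha, bonferroni = bonferroni,
                 min_internal = as.integer(min_internal),
                 min_terminal = as.integer(min_terminal),
                 max_depth = as.integer(max_depth),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "citree_controls")
}

# Association statistic of one predictor with y.
# Numeric x: absolute centered cross-product |sum (x - xbar)(y - ybar)|.
# Categorical x: between-group sum of squares, sum_g n_g (ybar_g - ybar)^2.
.assoc_stat_num <- function(xc, yc) abs(sum(xc * yc))
.assoc_stat_cat <- function(g, ng, y, ybar) {
  s <- rowsum(y, g)  # group sums, ordered by level
  sum((s / ng - ybar)^2 * ng)
}

#' Permutation p-value for the association of one predictor with yield
#'
#' Monte-Carlo permutation test of independence based on a linear
#' statistic: for numeric predictors the absolute centered cross-product
#' (equivalent to the absolute covariance), for categorical predictors
#' the between-group sum of squares of the response. The p-value is
#' `(1 + #{permuted stat >= observed}) / (n_perm + 1)`, which lies in
#' (0, 1] and is valid (slightly conservative) at any `n_perm`.
#' Constant `x` or constant `y` returns 1 by convention.
#'
#' @param x Numeric vector or factor/character predictor.
#' @param y Numeric response, same length as `x` (length >= 3).
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Optional integer seed (local to this call).
#' @return Permutation p-value in (0, 1].
#' @export
association_pvalue <- function(x, y, n_perm = 9999L, seed = NULL) {
  n <- length(y)
  if (length(x) != n || n < 3) stop("need length(x) == length(y) >= 3", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  if (stats::sd(y) == 0) return(1)
  yc <- y - mean(y)
  perm <- matrix(0L, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- sample.int(n)
  if (is.numeric(x)) {
    if (stats::sd(x) == 0) return(1)
    xc <- x - mean(x)
    obs <- .assoc_stat_num(xc, yc)
    stat <- abs(as.vector(crossprod(matrix(yc[perm], n), xc)))
  } else {
    g <- factor(x)
    if (nlevels(g) < 2) return(1)
    ng <- as.vector(table(g))
    obs <- .assoc_stat_cat(g, ng, y, mean(y))
    gm <- stats::model.matrix(~ g - 1)  # n x k indicator
    sums <- crossprod(gm, matrix(y[perm], n))  # k x n_perm group sums
    stat <- colSums((sums / ng - mean(y))^2 * ng)
  }
  tol <- 1e-12 * max(obs, 1)
  (1 + sum(stat >= obs - tol)) / (n_perm + 1)
}

# Preserve/restore the global RNG state around seeded helpers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Shared-permutation association p-values for all predictors at a node.
# X: data frame of predictors (numeric or factor); y: response.
# Returns raw p-values in column order.
.node_pvalues <- function(X, y, n_perm) {
  n <- length(y)
  yc <- y - mean(y)
  if (stats::sd(y) == 0) return(rep(1, ncol(X)))
  perm <- matrix(0L, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- sample.int(n)
  Yp <- matrix(yc[perm], n)  # centered permuted responses
  p <- numeric(ncol(X))
  num <- vapply(X, is.numeric, logical(1))
  if (any(num)) {
    Xc <- scale(as.matrix(X[, num, drop = FALSE]), center = TRUE, scale = FALSE)
    const <- apply(Xc, 2, function(v) all(v == 0))
    obs <- abs(as.vector(crossprod(Xc, yc)))
    stat <- abs(crossprod(Xc, Yp))  # p_num x n_perm
    tol <- 1e-12 * pmax(obs, 1)
    pn <- (1 + rowSums(stat >= obs - tol)) / (n_perm + 1)
    pn[const] <- 1
    p[num] <- pn
  }
  for (j in which(!num)) {
    g <- factor(X[[j]])
    if (nlevels(droplevels(g)) < 2) { p[j] <- 1; next }
    g <- droplevels(g)
    ng <- as.vector(table(g))
    gm <- stats::model.matrix(~ g - 1)
    obs <- .assoc_stat_cat(g, ng, y, mean(y))
    sums <- crossprod(gm, Yp + mean(y))
    stat <- colSums((sums / ng - mean(y))^2 * ng)
    tol <- 1e-12 * max(obs, 1)
    p[j] <- (1 + sum(stat >= obs - tol)) / (n_perm + 1)
  }
  p
}

#' Select the splitting variable at a tree node
#'
#' Computes permutation p-values for every candidate predictor, applies
#' the Bonferroni adjustment (multiplication by the number of
#' candidates, capped at 1), and returns the predictor with the smallest
#' p-value if it passes `alpha`; otherwise signals a stop. Ties are
#' broken by column order.
#'
#' @param X Data frame of candidate predictors at the node.
#' @param y Numeric response at the node.
#' @param controls A [citree_controls()] object.
#' @return `NULL` (global independence not rejected) or a list with
#'   `variable`, `p_adjusted`, and the vector of adjusted p-values.
#' @export
select_split_variable <- function(X, y, controls = citree_controls()) {
  p_raw <- .node_pvalues(X, y, controls$n_perm)
  p_adj <- if (controls$bonferroni) pmin(1, p_raw * ncol(X)) else p_raw
  names(p_adj) <- names(X)
  j <- which.min(p_adj)  # first minimum = column-order tie-break
  if (p_adj[j] > controls$alpha) return(NULL)
  list(variable = names(X)[j], p_adjusted = unname(p_adj[j]), p_all = p_adj)
}

#' Best binary split of a selected variable
#'
#' Among candidate cut points leaving at least `min_terminal`
#' observations on each side, selects the cut maximizing the
#' standardized two-sample mean-difference statistic (equivalently the
#' between-group sum of squares). Numeric thresholds are reported as the
#' midpoint of the adjacent observed values. Categorical variables are
#' ordered by their category mean response and searched as an ordinal
#' variable, which is exact for a least-squares split criterion; the
#' result is the set of levels routed left.
#'
#' @param x Selected predictor values (numeric or factor/character).
#' @param y Numeric response.
#' @param min_terminal Minimum observations on each side of the cut.
#' @return `NULL` if no admissible cut exists, else a list with `type`
#'   (`"numeric"` or `"factor"`), `threshold` (numeric) or `left_levels`
#'   (character), and the criterion value.
#' @export
best_binary_split <- function(x, y, min_terminal = 1L) {
  n <- length(y)
  if (is.numeric(x)) {
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cs <- cumsum(ys); S <- cs[n]
    k <- seq_len(n - 1L)
    ok <- k >= min_terminal & (n - k) >= min_terminal & xs[k] < xs[k + 1L]
    if (!any(ok)) return(NULL)
    # between-group SS: nL*nR/n * (meanL - meanR)^2, up to constants
    crit <- (cs[k] - k * S / n)^2 / (k * (n - k))
    crit[!ok] <- -Inf
    kk <- which.max(crit)
    list(type = "numeric", threshold = (xs[kk] + xs[kk + 1L]) / 2,
         criterion = crit[kk])
  } else {
    g <- droplevels(factor(x))
    if (nlevels(g) < 2) return(NULL)
    means <- tapply(y, g, mean)
    lev <- names(sort(means))  # order categories by mean response
    r <- as.numeric(factor(as.character(g), levels = lev))
    sp <- best_binary_split(r, y, min_terminal)
    if (is.null(sp)) return(NULL)
    list(type = "factor", left_levels = lev[seq_len(floor(sp$threshold))],
         criterion = sp$criterion)
  }
}

#' Fit a conditional-inference regression tree
#'
#' Recursive binary partitioning: at each node the global null of
#' independence between the response and all candidate predictors is
#' tested via Bonferroni-adjusted permutation tests; if rejected, the
#' strongest predictor is split at the cut maximizing the two-sample
#' criterion, subject to minimum node sizes and maximum depth.
#'
#' @param X Data frame of candidate predictors (numeric columns plus an
#'   optional categorical `state` column).
#' @param y Numeric response (yield, kg/ha).
#' @param controls A [citree_controls()] object.
#' @return Object of class `citree`: list with `nodes` (data frame of
#'   node id, parent, depth, n, mean, split variable/threshold/levels,
#'   adjusted p), `where` (leaf id per observation), and `controls`.
#' @export
fit_citree <- function(X, y, controls = citree_controls()) {
  stopifnot(is.data.frame(X), nrow(X) == length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(controls$seed)

  nodes <- list()
  where <- integer(length(y))
  next_id <- 1L

  build <- function(idx, depth, parent) {
    id <- next_id; next_id <<- next_id + 1L
    node <- list(id = id, parent = parent, depth = depth, n = length(idx),
                 mean = mean(y[idx]), split_var = NA_character_,
                 threshold = NA_real_, left_levels = NA_character_,
                 p_adjusted = NA_real_, left = NA_integer_, right = NA_integer_)
    make_leaf <- function() {
      nodes[[id]] <<- node
      where[idx] <<- id
      id
    }
    if (length(idx) < controls$min_internal || depth >= controls$max_depth) {
      return(make_leaf())
    }
    sel <- select_split_variable(X[idx, , drop = FALSE], y[idx], controls)
    if (is.null(sel)) return(make_leaf())
    sp <- best_binary_split(X[idx, sel$variable, drop = TRUE],
                            y[idx], controls$min_terminal)
    if (is.null(sp)) return(make_leaf())
    node$split_var <- sel$variable
    node$p_adjusted <- sel$p_adjusted
    xv <- X[idx, sel$variable, drop = TRUE]
    if (sp$type == "numeric") {
      node$threshold <- sp$threshold
      go_left <- xv <= sp$threshold
    } else {
      node$left_levels <- paste(sp$left_levels, collapse = "|")
      go_left <- as.character(xv) %in% sp$left_levels
    }
    nodes[[id]] <<- node  # placeholder; children filled in below
    lid <- build(idx[go_left], depth + 1L, id)
    rid <- build(idx[!go_left], depth + 1L, id)
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  build(seq_along(y), 1L, NA_integer_)

  nd <- do.call(rbind, lapply(nodes, function(nd) {
    data.frame(id = nd$id, parent = nd$parent, depth = nd$depth, n = nd$n,
               mean = nd$mean, split_var = nd$split_var,
               threshold = nd$threshold, left_levels = nd$left_levels,
               p_adjusted = nd$p_adjusted, left = nd$left, right = nd$right,
               stringsAsFactors = FALSE)
  }))
  structure(list(nodes = nd, where = where, controls = controls,
                 predictors = names(X)),
            class = "citree")
}

#' Predict from a conditional-inference tree
#'
#' Routes each row to its leaf and returns the leaf mean yield.
#'
#' @param tree A fitted [fit_citree()] object.
#' @param newdata Data frame containing the tree's predictor columns.
#' @return Numeric vector of predicted yields (kg/ha).
#' @export
predict_citree <- function(tree, newdata) {
  nd <- tree$nodes
  route1 <- function(row) {
    id <- 1L
    repeat {
      r <- nd[nd$id == id, ]
      if (is.na(r$split_var)) return(r$mean)
      x <- row[[r$split_var]]
      left <- if (!is.na(r$threshold)) {
        x <= r$threshold
      } else {
        as.character(x) %in% strsplit(r$left_levels, "|", fixed = TRUE)[[1]]
      }
      id <- if (left) r$left else r$right
    }
  }
  vapply(seq_len(nrow(newdata)), function(i) route1(newdata[i, , drop = FALSE]),
         numeric(1))
}

#' @export
print.citree <- function(x, digits = 3, ...) {
  nd <- x$nodes
  rec <- function(id, indent) {
    r <- nd[nd$id == id, ]
    pad <- strrep("  ", indent)
    if (is.na(r$split_var)) {
      cat(sprintf("%s* leaf [%d]: n = %d, mean yield = %.0f kg/ha\n",
                  pad, r$id, r$n, r$mean))
    } else {
      lab <- if (!is.na(r$threshold)) {
        sprintf("%s <= %.*g", r$split_var, digits, r$threshold)
      } else {
        sprintf("%s in {%s}", r$split_var, gsub("|", ", ", r$left_levels, fixed = TRUE))
      }
      cat(sprintf("%s[%d] %s (p = %.2g, n = %d)\n", pad, r$id, lab, r$p_adjusted, r$n))
      rec(r$left, indent + 1)
      rec(r$right, indent + 1)
    }
  }
  cat("Conditional-inference regression tree\n")
  rec(1L, 0)
  invisible(x)
}

#' Serialize a fitted tree to JSON
#'
#' @param tree A fitted [fit_citree()] object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
citree_to_json <- function(tree, path = NULL) {
  doc <- list(predictors = tree$predictors,
              controls = unclass(tree$controls),
              nodes = tree$nodes)
  js <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Within-stratum Vpd-yield slope with a state-homogeneity test
#'
#' Least-squares regression of yield on a named window feature within a
#' (tree-defined) stratum of state-year records. When two or more
#' states are present the model includes state intercepts, so the
#' reported slope is the common within-state slope — the quantity whose
#' homogeneity across states is then assessed by the state-by-predictor
#' interaction F-test. (A pooled slope without state intercepts would
#' be attenuated by between-state differences in the predictor's
#' climatological level.) With a single state the simple regression is
#' used.
#'
#' @param data Data frame of state-year records containing `yield`,
#'   `state` (optional), and the predictor column.
#' @param predictor Name of the feature column (e.g. `"vpd_mean_W3"`).
#' @param conf_level Confidence level for the slope interval.
#' @return List with `slope` (kg/ha per predictor unit), `ci` (length-2),
#'   `p_slope`, `n`, and `p_homogeneity` (NA when fewer than two states
#'   have at least two observations).
#' @export
node_vpd_slope <- function(data, predictor, conf_level = 0.95) {
  stopifnot(predictor %in% names(data), "yield" %in% names(data))
  x <- data[[predictor]]
  if (length(x) < 3) stop("stratum must have at least 3 records", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor: slope undefined", call. = FALSE)
  multi_state <- "state" %in% names(data) &&
    length(unique(data$state)) >= 2
  fit <- if (multi_state) {
    stats::lm(data$yield ~ x + factor(data$state))
  } else {
    stats::lm(data$yield ~ x)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = conf_level)
  p_hom <- NA_real_
  if ("state" %in% names(data)) {
    tab <- table(data$state)
    if (sum(tab >= 2) >= 2) {
      d2 <- data[data$state %in% names(tab)[tab >= 2], , drop = FALSE]
      st <- factor(d2$state)
      f0 <- stats::lm(d2$yield ~ d2[[predictor]] + st)
      f1 <- stats::lm(d2$yield ~ d2[[predictor]] * st)
      an <- stats::anova(f0, f1)
      p_hom <- an[["Pr(>F)"]][2]
    }
  }
  list(slope = unname(stats::coef(fit)["x"]),
       ci = as.numeric(ci),
       p_slope = sm$coefficients["x", "Pr(>|t|)"],
       n = length(x),
       p_homogeneity = p_hom)
}
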