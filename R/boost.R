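#' Controls for the L2 boosting model
#'
#' Defaults follow the tuned values used for the yield model: 600
#' boosting iterations at step length (shrinkage) 0.2, with an 85%/15%
#' train/test partition stratified by state within year.
#'
#' @param n_iter Number of boosting iterations.
#' @param step Learning rate (shrinkage) applied to each base-learner
#'   update, in (0, 1].
#' @param base_learner `"stump"` (depth-1 regression tree, the default;
#'   captures the threshold-like Vpd responses seen in the tree stage) or
#'   `"componentwise_linear"` (simple linear regression on one feature,
#'   whose boosted limit is the least-squares fit).
#' @param train_frac Fraction of records assigned to training.
#' @param seed Integer seed for the stratified split.
#' @return List of class `boost_controls`.
#' @export
boost_controls <- function(n_iter = 600L, step = 0.2,
                           base_learner = c("stump", "componentwise_linear"),
                           train_frac = 0.85, seed = 1L) {
  base_learner <- match.arg(base_learner)
  stopifnot(n_iter >= 0, step > 0, step <= 1, train_frac > 0, train_frac < 1)
  structure(list(n_iter = as.integer(n_iter), step = step,
                 base_learner = base_learner, train_frac = train_frac,
                 seed = as.integer(seed)),
            class = "boost_controls")
}

#' Stratified train/test split
#'
#' Partitions records into training and test sets with the training
#' proportion applied within each stratum (rounded to the nearest
#' count). Singleton strata go to the training set, with a message.
#'
#' @param data Data frame of records.
#' @param train_frac Training fraction in (0, 1).
#' @param strata Character vector of column names defining the strata
#'   (default: state within year).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return List with integer row indices `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(data, train_frac = 0.85,
                             strata = c("state", "year"), seed = 1L) {
  stopifnot(nrow(data) >= 2, all(strata %in% names(data)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  key <- interaction(data[, strata, drop = FALSE], drop = TRUE)
  train <- integer(0)
  singletons <- 0L
  for (lev in levels(key)) {
    idx <- which(key == lev)
    n <- length(idx)
    if (n == 1L) { train <- c(train, idx); singletons <- singletons + 1L; next }
    n_tr <- max(1L, min(n, round(train_frac * n)))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  if (singletons > 0) {
    message("stratified_split: ", singletons,
            " singleton stratum(-a) assigned to training")
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(data)), train))
}

#' Fit a component-wise L2 boosting model
#'
#' Functional gradient descent under squared-error loss: starting from
#' the training-mean offset, each iteration fits every candidate base
#' learner to the current residuals (the negative gradient), keeps the
#' one with the largest residual sum-of-squares reduction, and adds
#' `step` times its fitted function to the ensemble. No early stopping
#' is performed; the iteration count is fixed by the controls.
#'
#' @param X Data frame or matrix of numeric features (no missing values).
#' @param y Numeric response (kg/ha).
#' @param controls A [boost_controls()] object.
#' @return Object of class `boost_model`: `offset`, `learners` (data
#'   frame, one row per iteration), `base_learner`, `features`,
#'   `train_mse` (per-iteration training MSE), `controls`.
#' @export
fit_boost <- function(X, y, controls = boost_controls()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  n <- nrow(X); p <- ncol(X)
  feat <- colnames(X)
  if (is.null(feat)) feat <- paste0("x", seq_len(p))
  offset <- mean(y)
  r <- y - offset
  nu <- controls$step
  mse <- numeric(controls$n_iter)

  if (controls$n_iter == 0L) {
    return(structure(list(offset = offset, learners = NULL,
                          base_learner = controls$base_learner,
                          features = feat, train_mse = numeric(0),
                          controls = controls),
                     class = "boost_model"))
  }

  if (controls$base_learner == "componentwise_linear") {
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    ss <- colSums(Xc^2)
    usable <- ss > 0
    lj <- integer(controls$n_iter); lb <- numeric(controls$n_iter)
    for (it in seq_len(controls$n_iter)) {
      beta <- as.vector(crossprod(Xc, r)) / ifelse(usable, ss, Inf)
      red <- beta^2 * ss
      j <- which.max(red)
      fitj <- beta[j] * Xc[, j]
      r <- r - nu * fitj
      lj[it] <- j; lb[it] <- beta[j]
      mse[it] <- mean(r^2)
    }
    learners <- data.frame(iter = seq_len(controls$n_iter),
                           feature = feat[lj], beta = lb,
                           center = ctr[lj], stringsAsFactors = FALSE)
  } else {
    ords <- lapply(seq_len(p), function(j) order(X[, j]))
    Xs <- vapply(seq_len(p), function(j) X[ords[[j]], j], numeric(n))
    valid <- Xs[-n, , drop = FALSE] < Xs[-1L, , drop = FALSE]  # no cut inside ties
    k <- seq_len(n - 1L)
    lj <- integer(controls$n_iter); lt <- numeric(controls$n_iter)
    ll <- numeric(controls$n_iter); lr <- numeric(controls$n_iter)
    for (it in seq_len(controls$n_iter)) {
      Rs <- vapply(seq_len(p), function(j) r[ords[[j]]], numeric(n))
      cs <- apply(Rs, 2, cumsum)
      S <- cs[n, 1L]  # total residual sum, same for all columns
      csk <- cs[-n, , drop = FALSE]
      red <- csk^2 / k + (S - csk)^2 / (n - k)  # SSE reduction + const
      red[!valid] <- -Inf
      jk <- arrayInd(which.max(red), dim(red))
      kk <- jk[1L]; j <- jk[2L]
      if (!is.finite(red[kk, j])) break  # all features constant
      thr <- (Xs[kk, j] + Xs[kk + 1L, j]) / 2
      lmean <- csk[kk, j] / kk
      rmean <- (S - csk[kk, j]) / (n - kk)
      fitj <- ifelse(X[, j] <= thr, lmean, rmean)
      r <- r - nu * fitj
      lj[it] <- j; lt[it] <- thr; ll[it] <- lmean; lr[it] <- rmean
      mse[it] <- mean(r^2)
    }
    used <- which(lj > 0)
    learners <- data.frame(iter = used, feature = feat[lj[used]],
                           threshold = lt[used], left = ll[used],
                           right = lr[used], stringsAsFactors = FALSE)
    mse <- mse[used]
  }
  structure(list(offset = offset, learners = learners,
                 base_learner = controls$base_learner, features = feat,
                 train_mse = mse, controls = controls),
            class = "boost_model")
}

#' Predict from a boosting model
#'
#' Deterministic evaluation of the additive ensemble:
#' offset + sum over iterations of step x base-function value.
#'
#' @param model A fitted [fit_boost()] object.
#' @param newdata Data frame or matrix containing all model features.
#' @return Numeric vector of predicted yields (kg/ha).
#' @export
predict_boost <- function(model, newdata) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(model$features, names(newdata))
  if (length(miss)) {
    stop("newdata is missing feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pred <- rep(model$offset, nrow(newdata))
  L <- model$learners
  if (is.null(L) || nrow(L) == 0) return(pred)
  nu <- model$controls$step
  if (model$base_learner == "componentwise_linear") {
    for (i in seq_len(nrow(L))) {
      pred <- pred + nu * L$beta[i] * (newdata[[L$feature[i]]] - L$center[i])
    }
  } else {
    for (i in seq_len(nrow(L))) {
      pred <- pred + nu * ifelse(newdata[[L$feature[i]]] <= L$threshold[i],
                                 L$left[i], L$right[i])
    }
  }
  pred
}

#' Evaluate a boosting model on held-out records
#'
#' @param model A fitted [fit_boost()] object.
#' @param X Feature data for the held-out records.
#' @param y Observed responses.
#' @return List with `r2` (squared Pearson correlation between predicted
#'   and observed) and `rmse` (root mean squared error, kg/ha).
#' @export
evaluate_boost <- function(model, X, y) {
  pred <- predict_boost(model, X)
  r2 <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) 0 else stats::cor(pred, y)^2
  list(r2 = r2, rmse = sqrt(mean((y - pred)^2)))
}

#' Serialize a boosting model to JSON
#' @param model A fitted [fit_boost()] object.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
boost_to_json <- function(model, path = NULL) {
  doc <- list(offset = model$offset, base_learner = model$base_learner,
              step = model$controls$step, features = model$features,
              learners = model$learners)
  js <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
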