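# AdaBoost.R2 regression (Drucker's extension of AdaBoost to regression)
# with depth-limited regression trees as base learners. The base trees are
# fit by rpart with case weights; no installed package provides this
# boosting scheme for regression, so the boosting loop itself lives here.

#' Fit an AdaBoost.R2 regression ensemble
#'
#' Each round fits a weighted regression tree, converts absolute residuals
#' to linear losses \eqn{L_i = |e_i| / max_j |e_j|}, computes the average
#' loss \eqn{\bar L = \sum_i D_i L_i}, stops if \eqn{\bar L \ge 0.5}, sets
#' \eqn{\beta_t = \bar L / (1 - \bar L)} and reweights
#' \eqn{D_i \propto D_i \beta_t^{1 - L_i}}. Prediction is the weighted
#' median of the base-learner outputs under weights \eqn{\log(1/\beta_t)}.
#' The procedure is deterministic (weights are passed to the tree fitter
#' directly, no resampling).
#'
#' @param x feature matrix or data frame.
#' @param y numeric response.
#' @param n_estimators maximum number of boosting rounds.
#' @param max_depth base-tree depth.
#' @return A list of class \code{adaboost_r2}.
#' @export
adaboost_r2_fit <- function(x, y, n_estimators = 50, max_depth = 3) {
  x <- as.data.frame(x)
  n <- length(y)
  stopifnot(nrow(x) == n, n_estimators >= 1)
  D <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, minsplit = 2,
                               minbucket = 1, cp = 0, xval = 0,
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  df <- data.frame(x, .y = y)
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = D * n,
                        method = "anova", control = ctrl)
    pred <- stats::predict(fit, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax <= 0) {            # perfect fit: give it full confidence
      trees[[t]] <- fit
      betas[t] <- 1e-10
      break
    }
    L <- err / emax
    Lbar <- sum(D * L)
    if (Lbar >= 0.5) break
    beta <- Lbar / (1 - Lbar)
    trees[[t]] <- fit
    betas[t] <- beta
    D <- D * beta^(1 - L)
    D <- D / sum(D)
  }
  if (!length(trees)) {
    # fall back to a single unweighted tree so the model is never empty
    trees[[1]] <- rpart::rpart(.y ~ ., data = df, method = "anova",
                               control = ctrl)
    betas[1] <- 0.5
  }
  structure(list(trees = trees, betas = betas, feature_names = names(x)),
            class = "adaboost_r2")
}

weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  v[which(cw >= 0.5)[1L]]
}

#' Predict from an AdaBoost.R2 ensemble
#'
#' @param model an \code{adaboost_r2} fit.
#' @param x new data.
#' @return Numeric predictions (weighted median across base learners).
#' @export
adaboost_r2_predict <- function(model, x) {
  stopifnot(inherits(model, "adaboost_r2"))
  x <- as.data.frame(x)
  P <- vapply(model$trees, function(f) stats::predict(f, x),
              numeric(nrow(x)))
  if (nrow(x) == 1L) P <- matrix(P, nrow = 1L)
  w <- log(1 / model$betas)
  apply(P, 1L, weighted_median, w = w)
}
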