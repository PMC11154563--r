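# Hemoglobin regression suite: train/test split, exhaustive grid search
# with k-fold cross-validation, three model families, regression metrics,
# Bland-Altman agreement and Pearson correlation with pairwise-complete
# handling.

#' Assemble a regression dataset
#'
#' @param x feature matrix or data frame (8 or 9 columns in the standard
#'   configuration: per-wavelength AC/DC ratios, optionally mean pressure).
#' @param y hemoglobin concentrations (g/L).
#' @return A list of class \code{hb_dataset}.
#' @export
hb_dataset <- function(x, y) {
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) stop("row counts of x and y must match")
  if (anyNA(x) || anyNA(y)) stop("dataset must not contain missing values")
  structure(list(x = x, y = as.numeric(y)), class = "hb_dataset")
}

#' Random 7:3 train/test split
#'
#' @param ds an \code{\link{hb_dataset}} with at least 10 rows.
#' @param seed integer seed for the shuffle.
#' @return A list with \code{train} and \code{test} datasets; the test set
#'   holds \code{round(0.3 * n)} rows, the split is disjoint and
#'   exhaustive.
#' @export
split_7_3 <- function(ds, seed = 1) {
  stopifnot(inherits(ds, "hb_dataset"))
  n <- length(ds$y)
  if (n < 10) stop("need at least 10 rows to split")
  n_test <- round(0.3 * n)
  idx <- with_seed(seed, sample.int(n))
  test_idx <- sort(idx[seq_len(n_test)])
  train_idx <- sort(idx[-seq_len(n_test)])
  list(train = hb_dataset(ds$x[train_idx, , drop = FALSE], ds$y[train_idx]),
       test = hb_dataset(ds$x[test_idx, , drop = FALSE], ds$y[test_idx]))
}

#' Hyperparameter grid specification
#'
#' Family-appropriate exhaustive grids: tree ensembles search the number
#' of estimators (1-10) crossed with maximum depth (1-6); the neural
#' network searches activations and solvers over a fixed double-hidden-
#' layer architecture with an iteration cap of 10000.
#'
#' @param family one of "adaboost", "bpnn", "random_forest".
#' @param n_estimators,max_depth integer vectors (tree families).
#' @param activations,solvers character vectors (bpnn).
#' @param hidden two hidden-layer sizes (bpnn).
#' @param max_iter iteration cap (bpnn).
#' @return A list of class \code{grid_spec} with a data frame of
#'   parameter combinations.
#' @export
grid_spec <- function(family = c("adaboost", "bpnn", "random_forest"),
                      n_estimators = 1:10, max_depth = 1:6,
                      activations = c("identity", "logistic", "tanh", "relu"),
                      solvers = c("lbfgs", "sgd", "adam"),
                      hidden = c(16, 8), max_iter = 10000) {
  family <- match.arg(family)
  grid <- if (family == "bpnn") {
    expand.grid(activation = activations, solver = solvers,
                stringsAsFactors = FALSE)
  } else {
    expand.grid(n_estimators = n_estimators, max_depth = max_depth)
  }
  if (!nrow(grid)) stop("empty hyperparameter grid")
  structure(list(family = family, grid = grid, hidden = hidden,
                 max_iter = max_iter), class = "grid_spec")
}

fit_one <- function(family, params, train, hidden = c(16, 8),
                    max_iter = 10000, seed = 1) {
  switch(family,
    adaboost = adaboost_r2_fit(train$x, train$y,
                               n_estimators = params$n_estimators,
                               max_depth = params$max_depth),
    random_forest = with_seed(seed,
      randomForest::randomForest(x = train$x, y = train$y,
                                 ntree = params$n_estimators,
                                 maxnodes = 2^params$max_depth)),
    bpnn = mlp_fit(train$x, train$y, hidden = hidden,
                   activation = params$activation, solver = params$solver,
                   max_iter = max_iter, seed = seed),
    stop("unknown model family: ", family))
}

predict_one <- function(family, model, x) {
  switch(family,
    adaboost = adaboost_r2_predict(model, x),
    random_forest = as.numeric(stats::predict(model, x)),
    bpnn = mlp_predict(model, x))
}

#' Exhaustive grid search with k-fold cross-validation
#'
#' Evaluates every parameter combination by k-fold cross-validation on the
#' training set and selects the combination with the highest mean CV R^2;
#' ties are broken toward the smaller model (fewer estimators, then
#' shallower trees; first-listed option for the neural network).
#'
#' @param train an \code{\link{hb_dataset}}.
#' @param grid a \code{\link{grid_spec}}.
#' @param k number of folds (default 10); must not exceed the row count.
#' @param seed integer seed (fold assignment and stochastic fits).
#' @return A list with \code{best_params}, \code{best_cv} (mean R2/MSE/MAE
#'   at the optimum), \code{fold_metrics} (per-fold R2/MSE/MAE of the best
#'   combination) and \code{cv_table} (mean metrics per combination).
#' @export
grid_search_cv <- function(train, grid, k = 10, seed = 1) {
  stopifnot(inherits(train, "hb_dataset"), inherits(grid, "grid_spec"))
  n <- length(train$y)
  if (k > n) stop("k must not exceed the number of rows")
  folds <- with_seed(seed, {
    f <- rep(seq_len(k), length.out = n)
    sample(f)
  })
  g <- grid$grid
  res <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    params <- as.list(g[i, , drop = FALSE])
    fm <- matrix(NA_real_, k, 3,
                 dimnames = list(NULL, c("r2", "mse", "mae")))
    for (f in seq_len(k)) {
      tr <- hb_dataset(train$x[folds != f, , drop = FALSE],
                       train$y[folds != f])
      va <- hb_dataset(train$x[folds == f, , drop = FALSE],
                       train$y[folds == f])
      fit <- fit_one(grid$family, params, tr, grid$hidden, grid$max_iter,
                     seed = seed + f)
      pred <- predict_one(grid$family, fit, va$x)
      fm[f, ] <- regression_metrics(va$y, pred)
    }
    res[[i]] <- fm
  }
  mean_r2 <- vapply(res, function(m) mean(m[, "r2"]), numeric(1))
  ord <- order(-mean_r2)
  if (grid$family %in% c("adaboost", "random_forest"))
    ord <- order(-mean_r2, g$n_estimators, g$max_depth)
  best <- ord[1L]
  cv_table <- cbind(g, t(vapply(res, colMeans, numeric(3))))
  list(best_params = as.list(g[best, , drop = FALSE]),
       best_cv = colMeans(res[[best]]),
       fold_metrics = as.data.frame(res[[best]]),
       cv_table = cv_table)
}

#' Retrain on the full training set and score the test set
#'
#' @param family model family name.
#' @param params best hyperparameters (list).
#' @param train,test \code{\link{hb_dataset}} objects.
#' @param hidden,max_iter,seed see \code{\link{grid_spec}}.
#' @return A list with \code{model}, \code{predictions}, \code{metrics}
#'   (test-set R2/MSE/MAE) and \code{bland_altman}.
#' @export
fit_predict <- function(family, params, train, test, hidden = c(16, 8),
                        max_iter = 10000, seed = 1) {
  model <- fit_one(family, params, train, hidden, max_iter, seed)
  pred <- predict_one(family, model, test$x)
  list(model = model, predictions = pred,
       actual = test$y,
       metrics = regression_metrics(test$y, pred),
       bland_altman = bland_altman(test$y, pred))
}

#' Regression metrics
#'
#' Coefficient of determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, mean
#' squared error and mean absolute error. If the true values have zero
#' variance, R^2 is undefined and reported as \code{NA}.
#'
#' @param y_true,y_pred numeric vectors of equal nonzero length.
#' @return Named numeric vector \code{c(r2, mse, mae)}.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be equal-length, nonempty")
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  c(r2 = r2, mse = mean((y_true - y_pred)^2),
    mae = mean(abs(y_true - y_pred)))
}

#' Bland-Altman agreement summary
#'
#' Differences are predicted minus true; the 95% limits of agreement are
#' the mean difference plus/minus 1.96 population standard deviations.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return A list with \code{mean_diff}, \code{lower_limit},
#'   \code{upper_limit}, \code{outside_count}, and the \code{differences}
#'   and \code{means} used for plotting.
#' @export
bland_altman <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n < 2 || length(y_pred) != n)
    stop("need two equal-length vectors with at least 2 elements")
  d <- y_pred - y_true
  m <- mean(d)
  s <- sqrt(mean((d - m)^2))     # population SD
  lo <- m - 1.96 * s; hi <- m + 1.96 * s
  list(mean_diff = m, lower_limit = lo, upper_limit = hi,
       outside_count = sum(d < lo | d > hi),
       differences = d, means = (y_true + y_pred) / 2)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Correlations use all pairwise-complete observations; any pair with
#' fewer than \code{min_n} complete rows, or involving a zero-variance
#' column, is reported as \code{NA} (with a warning for zero variance).
#'
#' @param table numeric matrix or data frame with named columns.
#' @param min_n minimum pairwise-complete rows (default 3).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table, min_n = 3) {
  x <- as.matrix(as.data.frame(table))
  if (!is.numeric(x)) stop("all columns must be numeric")
  p <- ncol(x)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  warned <- FALSE
  for (i in seq_len(p)) for (j in i:p) {
    ok <- stats::complete.cases(x[, c(i, j), drop = FALSE])
    if (sum(ok) < min_n) next
    vi <- stats::var(x[ok, i]); vj <- stats::var(x[ok, j])
    if (!isTRUE(vi > 0) || !isTRUE(vj > 0)) { warned <- TRUE; next }
    out[i, j] <- out[j, i] <- stats::cor(x[ok, i], x[ok, j])
  }
  dg <- diag(out)
  dg[vapply(seq_len(p), function(i) {
    ok <- !is.na(x[, i]); sum(ok) >= min_n && isTRUE(stats::var(x[ok, i]) > 0)
  }, logical(1))] <- 1
  diag(out) <- dg
  if (warned) warning("zero-variance column(s): correlations reported as NA")
  out
}
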