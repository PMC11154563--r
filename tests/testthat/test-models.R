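test_that("7:3 split arithmetic and determinism", {
  set.seed(99)
  mk <- function(n) hb_dataset(data.frame(a = rnorm(n), b = rnorm(n)),
                               runif(n, 80, 160))
  sp <- split_7_3(mk(56), seed = 4)
  expect_equal(length(sp$train$y), 39)
  expect_equal(length(sp$test$y), 17)

  sp10 <- split_7_3(mk(10), seed = 4)
  expect_equal(length(sp10$train$y), 7)
  expect_equal(length(sp10$test$y), 3)

  ds <- mk(30)
  s1 <- split_7_3(ds, seed = 8)
  s2 <- split_7_3(ds, seed = 8)
  expect_identical(s1$train$y, s2$train$y)
  expect_identical(s1$test$x, s2$test$x)
  # disjoint and exhaustive
  expect_equal(sort(c(s1$train$y, s1$test$y)), sort(ds$y))

  expect_error(split_7_3(mk(9)), "at least 10")
})

test_that("regression metrics implement the standard definitions", {
  y <- c(100, 120)
  expect_equal(regression_metrics(y, y), c(r2 = 1, mse = 0, mae = 0))
  m <- regression_metrics(c(100, 120), c(110, 110))
  expect_equal(unname(m), c(0, 100, 10))
  ym <- c(95, 105, 130)
  m2 <- regression_metrics(ym, rep(mean(ym), 3))
  expect_equal(unname(m2[["r2"]]), 0)
  expect_true(is.na(regression_metrics(c(5, 5), c(4, 6))[["r2"]]))
  expect_error(regression_metrics(1:3, 1:4), "equal-length")
})

test_that("Bland-Altman limits use the population SD and 1.96", {
  b <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(b$mean_diff, 0)
  expect_equal(c(b$lower_limit, b$upper_limit), c(0, 0))
  expect_equal(b$outside_count, 0)

  b2 <- bland_altman(c(10, 10), c(12, 8))   # d = (+2, -2), pop SD = 2
  expect_equal(b2$mean_diff, 0)
  expect_equal(b2$upper_limit, 3.92)
  expect_equal(b2$lower_limit, -3.92)

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("about 5% of normal differences fall outside the 95% limits", {
  set.seed(31)
  y <- rnorm(100)
  b <- bland_altman(y, y + rnorm(100))
  expect_gte(b$outside_count, 1)
  expect_lte(b$outside_count, 9)
})

test_that("pearson matrix handles exact linearity and missing data", {
  x <- c(1, 2, 3)
  cm <- pearson_matrix(data.frame(x = x, up = 2 * x, down = c(6, 4, 2)))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(cm["x", "up"], 1)
  expect_equal(cm["x", "down"], -1)
  expect_true(isSymmetric(cm))
  expect_true(all(cm >= -1 & cm <= 1))

  expect_warning(cz <- pearson_matrix(data.frame(a = x, konst = c(2, 2, 2))),
                 "zero-variance")
  expect_true(is.na(cz["a", "konst"]))

  # fixture: hemoglobin vs creatinine over the complete rows, against the
  # direct covariance/SD formula
  tab <- load_clinical_fixture()
  sub <- filter_complete(tab, c("systolic_mmHg", "diastolic_mmHg",
                                "creatinine_umol_per_L", "urea_mmol_per_L"))
  h <- sub$hemoglobin_g_per_L; cr <- sub$creatinine_umol_per_L
  direct <- sum((h - mean(h)) * (cr - mean(cr))) /
    sqrt(sum((h - mean(h))^2) * sum((cr - mean(cr))^2))
  cm2 <- pearson_matrix(sub[, c("hemoglobin_g_per_L",
                                "creatinine_umol_per_L")])
  expect_equal(cm2[1, 2], direct, tolerance = 1e-12)
})

test_that("grid search returns the single point of a one-point grid", {
  set.seed(5)
  ds <- hb_dataset(data.frame(a = rnorm(20), b = rnorm(20)),
                   runif(20, 80, 160))
  g <- grid_spec("adaboost", n_estimators = 3, max_depth = 2)
  gs <- grid_search_cv(ds, g, k = 5, seed = 1)
  expect_equal(gs$best_params$n_estimators, 3)
  expect_equal(gs$best_params$max_depth, 2)
  expect_equal(nrow(gs$fold_metrics), 5)
})

test_that("leave-one-out cross-validation runs at the k = n boundary", {
  set.seed(6)
  n <- 12
  x <- data.frame(a = seq_len(n))
  ds <- hb_dataset(x, 100 + 2 * x$a)
  g <- grid_spec("adaboost", n_estimators = 2, max_depth = 1)
  gs <- grid_search_cv(ds, g, k = n, seed = 1)
  expect_equal(nrow(gs$fold_metrics), n)
  expect_error(grid_search_cv(ds, g, k = n + 1, seed = 1), "k must not")
})

test_that("tree families predict the constant on constant targets", {
  x <- data.frame(a = runif(12), b = runif(12))
  train <- hb_dataset(x, rep(123, 12))
  test <- hb_dataset(x[1:4, ], rep(123, 4))
  for (fam in c("adaboost", "random_forest")) {
    # randomForest warns about the degenerate constant response; that
    # degeneracy is exactly what this test exercises
    fp <- suppressWarnings(
      fit_predict(fam, list(n_estimators = 3, max_depth = 2),
                  train, test, seed = 2))
    expect_equal(fp$predictions, rep(123, 4), tolerance = 1e-9)
  }
})

test_that("a single stump forest is piecewise constant", {
  set.seed(7)
  x <- data.frame(a = runif(40))
  ds <- hb_dataset(x, 100 + 50 * (x$a > 0.5))
  fp <- suppressWarnings(
    fit_predict("random_forest", list(n_estimators = 1, max_depth = 1),
                ds, ds, seed = 3))
  expect_lte(length(unique(fp$predictions)), 2)
})

test_that("the neural network fits a linear map almost exactly", {
  set.seed(8)
  x <- data.frame(a = runif(40), b = runif(40))
  y <- 110 + 20 * x$a - 12 * x$b
  m <- mlp_fit(x, y, hidden = c(8, 4), activation = "identity",
               solver = "lbfgs", max_iter = 2000, seed = 1)
  pred <- mlp_predict(m, x)
  expect_gt(regression_metrics(y, pred)[["r2"]], 0.999)
})

test_that("boosted trees recover a noisy nonlinear response", {
  set.seed(9)
  x <- data.frame(a = runif(80, 80, 160))
  y <- x$a + rnorm(80, sd = 3)
  ds <- hb_dataset(x, y)
  sp <- split_7_3(ds, seed = 2)
  g <- grid_spec("adaboost", n_estimators = c(3, 6), max_depth = c(2, 4))
  gs <- grid_search_cv(sp$train, g, k = 5, seed = 2)
  expect_gt(gs$best_cv[["r2"]], 0.8)
  fp <- fit_predict("adaboost", gs$best_params, sp$train, sp$test, seed = 2)
  expect_gt(fp$metrics[["r2"]], 0.8)
})
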