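test_that("one cost-adjusted boosting round matches hand arithmetic", {
  # three samples, one poor (-1) with cost 0.8, stump separates perfectly
  x <- data.frame(f = c(1, 2, 3))
  y <- c(1, 1, -1)
  m <- adacost_fit(x, y, cost_poor = 0.8, cost_good = 0.2,
                   n_rounds = 1, seed = 1)
  # by hand: all correct, beta = 0.5 - 0.5c = (0.4, 0.4, 0.1),
  # r = mean(beta) = 0.3, alpha = 0.5*log(1.3/0.7),
  # D' ~ (1/3) exp(-alpha * beta), normalized
  alpha <- 0.5 * log(1.3 / 0.7)
  w <- exp(-alpha * c(0.4, 0.4, 0.1)) / 3
  w <- w / sum(w)
  expect_equal(m$alphas[1], alpha, tolerance = 1e-12)
  expect_equal(m$weights_trace[[1]], w, tolerance = 1e-12)
})

test_that("sample weights stay normalized every round", {
  qd <- quality_data()
  m <- adacost_fit(qd$x, qd$y, n_rounds = 12, seed = 3)
  for (D in m$weights_trace) expect_equal(sum(D), 1, tolerance = 1e-12)
})

test_that("zero costs reproduce AdaBoost's weak-learner selections", {
  sp <- sixpoint()
  ref <- adaboost_reference(sp$x, sp$y, rounds = 5, maxdepth = 1)
  expect_gte(length(ref), 3)
  m0 <- adacost_fit(sp$x, sp$y, cost_poor = 0, cost_good = 0,
                    n_rounds = length(ref), maxdepth = 1, seed = 1)
  expect_equal(lapply(m0$train_selection, unlist),
               lapply(ref, unlist))
})

test_that("boosting drives training error to zero on separable data", {
  x <- data.frame(a = c(1, 2, 3, 10, 11, 12), b = c(5, 4, 6, 5, 4, 6))
  y <- c(1, 1, 1, -1, -1, -1)
  m <- adacost_fit(x, y, n_rounds = 3, seed = 1)
  pred <- adacost_predict(m, x)
  expect_equal(pred$label, y)
})

test_that("prediction follows the weighted ensemble vote", {
  x <- data.frame(f = c(1, 2, 3, 4))
  y <- c(1, 1, -1, -1)
  m <- adacost_fit(x, y, n_rounds = 1, seed = 1)
  expect_length(m$alphas, 1)
  single <- adacost_predict(m, x)
  expect_equal(single$label, y)   # one perfect learner: prediction = learner
  # negating the learner weights flips every prediction
  m$alphas <- -m$alphas
  flipped <- adacost_predict(m, x)
  expect_equal(flipped$label, -single$label)

  expect_error(adacost_fit(x, rep(1, 4)), "both quality classes")
})

test_that("classification report implements the standard definitions", {
  expect_equal(classification_report(c(1, 1, -1), c(1, 1, -1), positive = 1),
               c(recall = 1, precision = 1, f1 = 1))
  r <- classification_report(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = 1)
  expect_equal(unname(r), c(0.5, 1, 2 / 3))
  expect_warning(
    r0 <- classification_report(c(1, 0, 1), c(0, 0, 0), positive = 1),
    "precision")
  expect_equal(unname(r0[["recall"]]), 0)
  expect_equal(unname(r0[["precision"]]), 0)
  expect_error(classification_report(numeric(0), numeric(0)), "empty")
})

test_that("raising the poor-class cost does not reduce poor recall", {
  qd <- quality_data()
  recall_at <- function(cp, cg) {
    m <- adacost_fit(qd$x, qd$y, cost_poor = cp, cost_good = cg,
                     n_rounds = 20, seed = 3)
    pred <- adacost_predict(m, qd$x)
    classification_report(qd$y, pred$label, positive = -1)[["recall"]]
  }
  expect_gte(recall_at(0.8, 0.2), recall_at(0, 0))
})

test_that("quality models survive a JSON round-trip", {
  qd <- quality_data()
  m <- adacost_fit(qd$x, qd$y, n_rounds = 8, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_quality_model(m, path)
  back <- read_quality_model(path)
  expect_equal(back$alphas, m$alphas, tolerance = 1e-12)
  p1 <- adacost_predict(m, qd$x)
  p2 <- adacost_predict(back, qd$x)
  expect_equal(p2$margin, p1$margin, tolerance = 1e-9)
  expect_identical(p2$label, p1$label)
})
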