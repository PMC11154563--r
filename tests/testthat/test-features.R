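brute_sliding <- function(x, w) {
  m <- length(x) - w + 1
  t(vapply(seq_len(m), function(i) {
    win <- x[i:(i + w - 1)]
    c(mean = mean(win), variance = mean((win - mean(win))^2))
  }, numeric(2)))
}

test_that("sliding mean/variance recursion matches direct summation", {
  sw <- sliding_mean_variance(c(5, 5, 5, 5), 2)
  expect_equal(sw$mean, rep(5, 3))
  expect_equal(sw$variance, rep(0, 3))

  sw <- sliding_mean_variance(c(1, 2, 3, 4), 2)
  expect_equal(sw$mean, c(1.5, 2.5, 3.5))
  expect_equal(sw$variance, rep(0.25, 3))

  set.seed(10)
  x <- runif(1000)
  got <- sliding_mean_variance(x, 50)
  ref <- brute_sliding(x, 50)
  expect_lt(max(abs(got$mean - ref[, "mean"]) / pmax(abs(ref[, "mean"]), 1)),
            1e-9)
  expect_lt(max(abs(got$variance - ref[, "variance"]) /
                  pmax(abs(ref[, "variance"]), 1)), 1e-9)

  expect_error(sliding_mean_variance(x, 1), "window")
  expect_error(sliding_mean_variance(x, 1001), "window")
})

test_that("minimum-variance window selection enumerates correctly", {
  r <- select_min_variance_mean(c(10, 10, 10, 2))
  expect_equal(r$window, 2)
  expect_equal(r$mean, 10)
  expect_equal(r$variance, 0)
  expect_equal(r$start, 1)   # tie among (10,10) windows: lowest start

  r <- select_min_variance_mean(c(7, 7, 7))
  expect_equal(r$mean, 7)
  expect_equal(r$variance, 0)

  # length 3: floor(3/2)=1 clamps to 2; windows (8,7) and (7,3)
  r <- select_min_variance_mean(c(8, 7, 3))
  expect_equal(r$window, 2)
  expect_equal(r$mean, 7.5)
  expect_equal(r$variance, 0.25)

  expect_error(select_min_variance_mean(5), "at least 2")
})

test_that("AC estimator suppresses appended corrupted beats", {
  amps <- c(10.2, 10.1, 10.0, 9.9, 10.05, 10.15, 9.95, 10.08, 10.12, 9.98)
  base <- ac_from_amplitudes(amps, amps)
  # append one grossly low amplitude (10% corruption)
  poisoned <- ac_from_amplitudes(c(amps, 0.5), c(amps, 0.5))
  expect_equal(poisoned$ac, base$ac, tolerance = 1e-9)

  # identical constants in both sets: equal weights under the variance floor
  const <- ac_from_amplitudes(rep(4, 6), rep(4, 6))
  expect_equal(const$ac, 4)
  expect_equal(const$min_window_variance, 0)
})

test_that("DC estimator reads the stable trough level", {
  # constant baseline: troughs all at the same level
  trace <- rep(100, 50)
  lm <- list(troughs = c(5, 15, 25, 35, 45))
  expect_equal(extract_dc(trace, lm), 100)

  # one drift-corrupted trough is excluded by the min-variance window
  trace2 <- rep(100, 60)
  trace2[55] <- 140
  lm2 <- list(troughs = c(5, 15, 25, 35, 45, 55))
  expect_equal(extract_dc(trace2, lm2), 100)

  expect_error(extract_dc(trace, list(troughs = 5L)), "troughs")
})

test_that("extractor recovers simulator ground truth on clean records", {
  sim <- clean_sim()
  fx <- clean_features()
  ch <- fx$channels
  expect_equal(nrow(ch), 8)
  expect_true(all(is.finite(fx$features)))
  rel <- function(est, tru) abs(est / tru - 1)
  expect_lt(max(rel(ch$ac, sim$truth$ac)), 0.02)
  expect_lt(max(rel(ch$dc, sim$truth$dc)), 0.02)
  expect_lt(max(rel(ch$ratio, sim$truth$ratio)), 0.02)
})

test_that("features are scale-equivariant in intensity", {
  sim <- clean_sim()
  x <- sim$record$channels[, 3]
  f1 <- extract_channel_features(x, 500)
  k <- 3.7
  f2 <- extract_channel_features(k * x, 500)
  expect_equal(f2$ac, k * f1$ac, tolerance = 1e-9)
  expect_equal(f2$dc, k * f1$dc, tolerance = 1e-9)
  expect_equal(f2$ratio, f1$ratio, tolerance = 1e-9)
})

test_that("ratio features order by hemoglobin concentration", {
  mk <- function(hb) {
    cfg <- sim_config(hb_g_per_L = hb, noise_sd = 0, drift_amp = 0,
                      duration_s = 6, seed = 13)
    extract_features(simulate_ppg(cfg)$record,
                     include_pressure = FALSE)$features
  }
  expect_true(all(mk(150) > mk(90)))
})

test_that("feature vector layout follows the model-input convention", {
  fx <- clean_features()
  expect_length(fx$features, 9)
  expect_equal(names(fx$features)[9], "mean_pressure")
  expect_false(is.unsorted(fx$channels$wavelength_nm[1:7]))
  expect_true(fx$channels$broadband[8])

  rec <- clean_sim()$record
  rec$pressure <- rep(3, length(rec$pressure))
  fx2 <- extract_features(rec)
  expect_equal(unname(fx2$features["mean_pressure"]), 3)
})
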