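# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Noise-free simulated record with ground truth (extractor oracle).
clean_sim <- function() cached("clean_sim", function() {
  cfg <- sim_config(noise_sd = 0, drift_amp = 0, artifact_rate = 0,
                    seed = 42)
  simulate_ppg(cfg)
})

clean_features <- function() cached("clean_features", function() {
  extract_features(clean_sim()$record)
})

# Labelled 100-record cohort (70 good / 30 poor) and its quality features.
quality_cohort <- function() cached("quality_cohort", function() {
  simulate_cohort(100, quality_mix = 0.3, seed = 5)
})

quality_data <- function() cached("quality_data", function() {
  quality_dataset(quality_cohort())
})

# 60-record clean cohort with extracted 9-feature matrix (end-to-end).
e2e_data <- function() cached("e2e_data", function() {
  cohort <- simulate_cohort(60, hb_range = c(80, 160), seed = 1)
  X9 <- do.call(rbind, lapply(cohort, function(r)
    extract_features(r$record, include_pressure = TRUE)$features))
  hb <- vapply(cohort, function(r) attr(r$truth, "hb_g_per_L"), numeric(1))
  list(X9 = X9, hb = hb)
})

# Reference AdaBoost (standard update) over the same rpart weak learners,
# used as the independent oracle for the all-costs-zero comparison.
adaboost_reference <- function(x, y, rounds, maxdepth = 1) {
  D <- rep(1 / length(y), length(y))
  sel <- list()
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, minsplit = 2,
                               minbucket = 1, cp = 0, xval = 0,
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  df <- data.frame(x, .y = factor(y, levels = c(-1, 1)))
  for (t in seq_len(rounds)) {
    fit <- rpart::rpart(.y ~ ., df, weights = D * nrow(df),
                        method = "class", control = ctrl)
    h <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(D[h != y])
    if (err >= 0.5 || err == 0) break
    alpha <- 0.5 * log((1 - err) / err)
    D <- D * exp(-alpha * y * h)
    D <- D / sum(D)
    sel[[t]] <- list(var = as.character(fit$frame$var[1]),
                     threshold = unname(fit$splits[1, "index"]))
  }
  sel
}

# Six-point dataset on which stump selection sequences are compared.
sixpoint <- function() {
  list(x = data.frame(f1 = c(9, 3, 5, 6, 1, 7),
                      f2 = c(6, 3, 4, 7, 9, 2)),
       y = c(1, -1, 1, -1, -1, 1))
}
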