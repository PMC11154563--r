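# End-to-end orchestration: simulate -> extract -> quality gate ->
# train/evaluate, persisted to a run directory with seeds and counts
# logged at every stage.

#' Pipeline configuration
#'
#' @param out_dir run directory (created if missing).
#' @param n_records cohort size.
#' @param hb_range hemoglobin range (g/L) for the simulated cohort.
#' @param quality_mix fraction of poor-quality records simulated.
#' @param quality_gate drop records the quality classifier flags as poor
#'   before regression?
#' @param feature_mode 8 (ratios only) or 9 (ratios + mean pressure).
#' @param family regression family for the final model.
#' @param grid a \code{\link{grid_spec}}; default a compact tree grid.
#' @param k folds for cross-validation.
#' @param seed master seed; every stage derives its seed from it.
#' @param cost_poor,cost_good AdaCost class costs.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, n_records = 60, hb_range = c(80, 160),
                            quality_mix = 0, quality_gate = quality_mix > 0,
                            feature_mode = 9,
                            family = "adaboost",
                            grid = grid_spec("adaboost",
                                             n_estimators = c(2, 4, 6, 8, 10),
                                             max_depth = c(2, 4, 6)),
                            k = 10, seed = 1,
                            cost_poor = 0.8, cost_good = 0.2) {
  stopifnot(feature_mode %in% c(8, 9))
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full hemoglobin-estimation pipeline
#'
#' Simulates a labelled cohort, extracts per-record quality and regression
#' features, optionally gates out records the AdaCost classifier flags as
#' poor, splits 7:3, grid-searches the regression family with k-fold
#' cross-validation, retrains on the full training set and evaluates on
#' the held-out test set. All intermediates (features, quality model,
#' report) are written under \code{cfg$out_dir}; the run is deterministic
#' given the config.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return The report list, invisibly (also written as
#'   \code{report.json}).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "ppghb pipeline, seed ", cfg$seed,
           ", n_records ", cfg$n_records)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("simulate",
    simulate_cohort(cfg$n_records, cfg$hb_range,
                    quality_mix = cfg$quality_mix, seed = cfg$seed))
  log_line(logf, "simulated ", length(cohort), " records (",
           sum(vapply(cohort, function(r) r$quality == "poor", logical(1))),
           " labelled poor)")

  keep <- rep(TRUE, length(cohort))
  if (cfg$quality_gate) {
    qd <- stage("quality_features", quality_dataset(cohort))
    qm <- stage("quality_train",
      adacost_fit(qd$x, qd$y, cost_poor = cfg$cost_poor,
                  cost_good = cfg$cost_good, seed = cfg$seed))
    write_quality_model(qm, file.path(cfg$out_dir, "quality_model.json"))
    pred <- adacost_predict(qm, qd$x)
    keep <- pred$label > 0
    log_line(logf, "quality gate kept ", sum(keep), " / ", length(keep),
             " records")
  }

  feats <- list(); hb <- numeric(0); kept_ids <- integer(0)
  for (i in which(keep)) {
    fx <- stage(paste0("extract record ", i),
                extract_features(cohort[[i]]$record,
                                 include_pressure = cfg$feature_mode == 9))
    feats[[length(feats) + 1L]] <- fx$features
    hb <- c(hb, attr(cohort[[i]]$truth, "hb_g_per_L"))
    kept_ids <- c(kept_ids, i)
  }
  X <- do.call(rbind, feats)
  fdf <- data.frame(record = kept_ids, X, hemoglobin_g_per_L = hb)
  utils::write.csv(fdf, file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)
  log_line(logf, "extracted ", nrow(X), " feature vectors of length ",
           ncol(X))

  ds <- hb_dataset(X, hb)
  sp <- stage("split", split_7_3(ds, seed = cfg$seed))
  gs <- stage("grid_search",
              grid_search_cv(sp$train, cfg$grid, k = min(cfg$k,
                             length(sp$train$y)), seed = cfg$seed))
  log_line(logf, "best params: ",
           paste(names(gs$best_params), unlist(gs$best_params),
                 sep = "=", collapse = ", "),
           " (mean CV R2 ", round(gs$best_cv[["r2"]], 3), ")")
  fp <- stage("fit_predict",
              fit_predict(cfg$family, gs$best_params, sp$train, sp$test,
                          hidden = cfg$grid$hidden,
                          max_iter = cfg$grid$max_iter, seed = cfg$seed))
  report <- list(
    seed = cfg$seed, n_records = cfg$n_records,
    n_kept = length(kept_ids), feature_mode = cfg$feature_mode,
    family = cfg$family, best_params = gs$best_params,
    cv = list(mean = as.list(gs$best_cv),
              folds = gs$fold_metrics),
    test = list(metrics = as.list(fp$metrics),
                predictions = fp$predictions, actual = fp$actual),
    bland_altman = fp$bland_altman[c("mean_diff", "lower_limit",
                                     "upper_limit", "outside_count")])
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  log_line(logf, "test R2 ", round(fp$metrics[["r2"]], 3),
           ", MAE ", round(fp$metrics[["mae"]], 2), " g/L")
  invisible(report)
}
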