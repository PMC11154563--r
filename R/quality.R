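# Cost-sensitive boosting (AdaCost) signal-quality index.
#
# AdaCost modifies the AdaBoost weight update with a cost-adjustment
# function so that misclassifying a high-cost sample (a poor-quality
# signal passed as satisfactory) inflates that sample's weight more than
# a plain AdaBoost update would:
#   D_{t+1}(i) ~ D_t(i) * exp(-alpha_t * y_i * h_t(x_i) * beta_i)
#   beta_i = 0.5 - 0.5*c_i if classified correctly,
#            0.5 + 0.5*c_i if misclassified,   c_i in [0, 1]
#   alpha_t = 0.5 * log((1 + r) / (1 - r)),  r = sum_i D(i) y_i h(x_i) beta_i

rpart_ctrl <- function(maxdepth)
  rpart::rpart.control(maxdepth = maxdepth, minsplit = 2, minbucket = 1,
                       cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0,
                       usesurrogate = 0)

# Fit a depth-limited classification tree with case weights and convert it
# to a compact, JSON-serializable node table.
weak_fit <- function(x, y, w, maxdepth = 2) {
  df <- data.frame(x, .y = factor(y, levels = c(-1, 1)))
  fit <- rpart::rpart(.y ~ ., data = df, weights = w * nrow(df),
                      method = "class", control = rpart_ctrl(maxdepth))
  frame <- fit$frame
  nodes <- as.integer(row.names(frame))
  leaf <- frame$var == "<leaf>"
  ylev <- as.numeric(attr(fit, "ylevels"))
  tbl <- data.frame(node = nodes,
                    var = as.character(frame$var),
                    threshold = NA_real_, go_left_if_less = NA,
                    pred = ylev[frame$yval])
  if (any(!leaf)) {
    sp <- fit$splits
    tbl$threshold[!leaf] <- sp[seq_len(sum(!leaf)), "index"]
    tbl$go_left_if_less[!leaf] <- sp[seq_len(sum(!leaf)), "ncat"] < 0
  }
  tbl
}

weak_predict <- function(tbl, x) {
  x <- as.data.frame(x)
  apply(x, 1L, function(row) {
    node <- 1L
    repeat {
      i <- match(node, tbl$node)
      if (tbl$var[i] == "<leaf>") return(tbl$pred[i])
      left <- if (tbl$go_left_if_less[i])
        row[[tbl$var[i]]] < tbl$threshold[i]
      else row[[tbl$var[i]]] >= tbl$threshold[i]
      node <- if (left) 2L * node else 2L * node + 1L
      if (!node %in% tbl$node) { node <- node %/% 2L; i <- match(node, tbl$node)
        return(tbl$pred[i]) }
    }
  })
}

#' Fit an AdaCost signal-quality classifier
#'
#' Boosts depth-limited decision trees (weighted-Gini splits) with the
#' cost-adjusted weight update above. Samples of the poor-quality class
#' carry a higher cost, so a poor signal slipping through as satisfactory
#' is penalized hardest; with all costs zero the update reduces to an
#' AdaBoost-style update with a constant 0.5 margin scale.
#'
#' @param x feature matrix or data frame.
#' @param y labels: +1 (satisfactory) / -1 (poor), or a factor with
#'   levels \code{c("good", "poor")}.
#' @param cost_poor,cost_good misclassification costs in [0, 1] assigned
#'   to the poor and satisfactory class.
#' @param n_rounds maximum number of boosting rounds.
#' @param maxdepth weak-learner tree depth.
#' @param seed integer seed (the procedure is deterministic; the seed
#'   guards any tie-breaking randomness inside the tree fitter).
#' @return A list of class \code{adacost_model}: \code{weak_learners}
#'   (node tables), \code{alphas}, \code{cost_map}, \code{feature_names},
#'   \code{weights_trace} (per-round normalized sample weights) and
#'   \code{train_selection} (split variable and threshold per round).
#' @export
adacost_fit <- function(x, y, cost_poor = 0.8, cost_good = 0.2,
                        n_rounds = 20, maxdepth = 2, seed = 1) {
  x <- as.data.frame(x)
  y <- quality_labels_pm1(y)
  if (length(unique(y)) < 2)
    stop("both quality classes must be present in the training data")
  if (n_rounds < 1) stop("n_rounds must be at least 1")
  stopifnot(cost_poor >= 0, cost_poor <= 1, cost_good >= 0, cost_good <= 1)
  cost <- ifelse(y < 0, cost_poor, cost_good)
  n <- length(y)
  D <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  trace <- list(); selection <- list()
  with_seed(seed, {
    for (t in seq_len(n_rounds)) {
      tbl <- weak_fit(x, y, D, maxdepth)
      h <- weak_predict(tbl, x)
      err <- sum(D[h != y])
      if (err >= 0.5) break   # degenerate weak learner: stop with what we have
      correct <- h == y
      beta <- ifelse(correct, 0.5 - 0.5 * cost, 0.5 + 0.5 * cost)
      u <- y * h * beta
      r <- sum(D * u)
      if (r <= 0) break
      alpha <- 0.5 * log((1 + r) / (1 - r))
      D <- D * exp(-alpha * u)
      D <- D / sum(D)
      learners[[t]] <- tbl
      alphas[t] <- alpha
      trace[[t]] <- D
      first_split <- tbl[tbl$var != "<leaf>", ][1, ]
      selection[[t]] <- list(var = first_split$var,
                             threshold = first_split$threshold)
      if (err == 0) break   # separable: ensemble already pure
    }
  })
  if (!length(learners))
    stop("no usable weak learner could be fit (degenerate data)")
  structure(list(weak_learners = learners, alphas = alphas,
                 cost_map = c(poor = cost_poor, good = cost_good),
                 feature_names = names(x),
                 weights_trace = trace, train_selection = selection),
            class = "adacost_model")
}

quality_labels_pm1 <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    if (!all(y %in% c("good", "poor")))
      stop("factor labels must be 'good'/'poor'")
    ifelse(y == "poor", -1, 1)
  } else {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be +1/-1")
    as.numeric(y)
  }
}

#' Score samples with an AdaCost model
#'
#' @param model an \code{adacost_model}.
#' @param x feature matrix or data frame with the training columns.
#' @return A data frame with the ensemble \code{margin}
#'   (\eqn{\sum_t \alpha_t h_t(x)}) and the predicted \code{label}
#'   (+1 satisfactory / -1 poor; ties resolve to +1).
#' @export
adacost_predict <- function(model, x) {
  stopifnot(inherits(model, "adacost_model"))
  x <- as.data.frame(x)
  miss <- setdiff(model$feature_names, names(x))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  H <- vapply(seq_along(model$weak_learners),
              function(t) model$alphas[t] *
                weak_predict(model$weak_learners[[t]], x),
              numeric(nrow(x)))
  margin <- if (nrow(x) == 1L) sum(H) else rowSums(as.matrix(H))
  data.frame(margin = margin, label = ifelse(margin < 0, -1, 1))
}

#' Classification metrics for quality assessment
#'
#' Recall, precision and F1 with the stated positive class. When no
#' positive predictions exist, precision is undefined and reported as 0
#' with a warning (and likewise F1).
#'
#' @param y_true,y_pred label vectors (same coding).
#' @param positive the positive-class label (default -1: the poor-quality
#'   class, which the screening task must not miss).
#' @return A named numeric vector \code{c(recall, precision, f1)}.
#' @export
classification_report <- function(y_true, y_pred, positive = -1) {
  if (!length(y_true)) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  if (tp + fp == 0) {
    warning("no positive predictions: precision undefined, reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Quality features for one record
#'
#' Per-record pooling of per-channel quality features: every channel is
#' summarized by its minimum window variance normalized by its squared DC
#' (a scale-free dispersion of the beat amplitudes) plus its landmark
#' counts, and the record is represented by its worst channel (largest
#' normalized variance). Channels whose extraction fails outright are
#' assigned a sentinel normalized variance of 1 and zero landmark counts,
#' so unusable records rank worst instead of erroring.
#'
#' @param rec a \code{\link{ppg_record}}.
#' @param ... passed to \code{\link{extract_channel_features}}.
#' @return Named numeric vector \code{c(norm_min_window_variance,
#'   n_peaks, n_troughs)}.
#' @export
quality_features <- function(rec, ...) {
  stopifnot(inherits(rec, "ppg_record"))
  k <- ncol(rec$channels)
  per_ch <- lapply(seq_len(k), function(ch) {
    r <- tryCatch(extract_channel_features(rec$channels[, ch], rec$fs_hz, ...),
                  error = function(e) NULL)
    if (is.null(r))
      return(c(v = 1, n_peaks = 0, n_troughs = 0))
    c(v = min(r$min_window_variance / r$dc^2, 1),
      n_peaks = r$n_peaks, n_troughs = r$n_troughs)
  })
  m <- do.call(rbind, per_ch)
  worst <- which.max(m[, "v"])
  c(norm_min_window_variance = unname(m[worst, "v"]),
    n_peaks = unname(m[worst, "n_peaks"]),
    n_troughs = unname(m[worst, "n_troughs"]))
}

#' Assemble a quality-classification dataset from a simulated cohort
#'
#' @param cohort list as returned by \code{\link{simulate_cohort}}.
#' @param ... passed to \code{\link{quality_features}}.
#' @return A list with feature matrix \code{x}, labels \code{y} (+1 good /
#'   -1 poor) and the original factor \code{quality}.
#' @export
quality_dataset <- function(cohort, ...) {
  x <- do.call(rbind, lapply(cohort, function(r) quality_features(r$record, ...)))
  quality <- factor(vapply(cohort, function(r) as.character(r$quality),
                           character(1)), levels = c("good", "poor"))
  list(x = as.data.frame(x), y = quality_labels_pm1(quality),
       quality = quality)
}

#' Persist an AdaCost model as a versioned JSON document
#'
#' @param model an \code{adacost_model}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_quality_model <- function(model, path) {
  stopifnot(inherits(model, "adacost_model"))
  doc <- list(format = "ppghb-quality-model", version = 1L,
              alphas = model$alphas, cost_map = as.list(model$cost_map),
              feature_names = model$feature_names,
              weak_learners = model$weak_learners)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load an AdaCost model from JSON
#'
#' @param path path written by \code{\link{write_quality_model}}.
#' @return An \code{adacost_model}.
#' @export
read_quality_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "ppghb-quality-model"))
    stop("not a ppghb quality model document: ", path)
  learners <- lapply(doc$weak_learners, function(w) {
    n <- length(w$node)
    col <- function(v, cast) {
      if (is.null(v) || !length(v)) return(cast(rep(NA, n)))
      v[vapply(v, is.null, logical(1))] <- NA
      cast(unlist(v))
    }
    data.frame(node = col(w$node, as.integer),
               var = col(w$var, as.character),
               threshold = col(w$threshold, as.numeric),
               go_left_if_less = col(w$go_left_if_less, as.logical),
               pred = col(w$pred, as.numeric))
  })
  structure(list(weak_learners = learners, alphas = doc$alphas,
                 cost_map = unlist(doc$cost_map),
                 feature_names = doc$feature_names,
                 weights_trace = list(), train_selection = list()),
            class = "adacost_model")
}
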