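# Sliding-window-variance selection of the pulsatile (AC) and static (DC)
# intensity components and the per-channel AC/DC ratio.

#' Sliding mean and population variance
#'
#' Means and population variances of every contiguous window of
#' \code{window} elements, computed with O(1) recursive updates per shift:
#' when the window slides by one, the mean is updated from the difference
#' of the entering and leaving elements, and the variance from an exact
#' algebraic rearrangement of the same shift. Values equal the direct
#' summation definitions (mean \eqn{A_n}, population variance \eqn{R_n}
#' over the window) up to floating-point rounding.
#'
#' @param x numeric sequence.
#' @param window window size \eqn{\Delta n}, between 2 and
#'   \code{length(x)}.
#' @return A data frame with one row per window start: \code{start},
#'   \code{mean}, \code{variance}.
#' @export
sliding_mean_variance <- function(x, window) {
  n <- length(x)
  if (window < 2 || window > n)
    stop("window must lie between 2 and length(x)")
  m <- n - window + 1L
  means <- numeric(m)
  vars <- numeric(m)
  a <- mean(x[seq_len(window)])
  r <- sum((x[seq_len(window)] - a)^2) / window
  means[1L] <- a; vars[1L] <- max(r, 0)
  if (m > 1L) {
    for (k in 2:m) {
      x_out <- x[k - 1L]
      x_in <- x[k + window - 1L]
      a_new <- a + (x_in - x_out) / window
      # exact shift update of the population variance:
      # R' = R + (x_in - x_out) * (x_in + x_out - A - A') / window
      r <- r + (x_in - x_out) * (x_in + x_out - a - a_new) / window
      a <- a_new
      means[k] <- a
      vars[k] <- max(r, 0)
    }
  }
  data.frame(start = seq_len(m), mean = means, variance = vars)
}

#' Minimum-variance window mean
#'
#' Slides a window of half the sequence length (at least 2) over the
#' sequence, picks the window with the smallest variance (ties broken by
#' the lowest start index) and returns that window's mean and variance.
#' Applied to sorted amplitude or trough sequences, this selects the most
#' self-consistent run of values and suppresses outliers.
#'
#' @param values numeric sequence (usually sorted), length >= 2.
#' @param window window size; default \code{max(2, floor(length(values)/2))}.
#' @return A list with \code{mean}, \code{variance}, \code{start},
#'   \code{window}.
#' @export
select_min_variance_mean <- function(values,
                                     window = max(2L, length(values) %/% 2L)) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  window <- max(2L, as.integer(window))
  if (window > n) window <- n
  sw <- sliding_mean_variance(values, window)
  # lowest start index among (near-)ties; the tolerance is relative to the
  # squared signal scale so the selection is scale-equivariant and immune
  # to last-digit rounding when many windows are equally flat
  vmin <- min(sw$variance)
  tol <- 1e-9 * mean(abs(values))^2
  best <- which(sw$variance <= vmin + tol)[1L]
  list(mean = sw$mean[best], variance = sw$variance[best],
       start = best, window = window)
}

# Peak-to-trough amplitude sets from alternating landmarks:
#   set A: each peak minus its preceding trough
#   set B: each peak minus its following trough
amplitude_sets <- function(x, lm) {
  a <- numeric(0); b <- numeric(0)
  for (p in lm$peaks) {
    prev_t <- lm$troughs[lm$troughs < p]
    next_t <- lm$troughs[lm$troughs > p]
    if (length(prev_t)) a <- c(a, x[p] - x[max(prev_t)])
    if (length(next_t)) b <- c(b, x[p] - x[min(next_t)])
  }
  list(a = a, b = b)
}

top_half <- function(values) {
  v <- sort(values, decreasing = TRUE)
  keep <- max(2L, length(v) %/% 2L)
  v[seq_len(min(keep, length(v)))]
}

#' Pulsatile amplitude from two beat-amplitude sets
#'
#' Core of the AC estimator: each amplitude set is sorted descending and
#' truncated to its first half — the larger amplitudes correspond to the
#' systolic rise, the discarded half to diastolic sub-wave heights and
#' corrupted beats — then the minimum-variance window of each truncated
#' set yields one mean, and the two means are combined by inverse-variance
#' weighting (variance floored at 1e-12 so two zero-variance estimates
#' average with equal weight). Appending a small fraction of grossly
#' corrupted (low) amplitudes leaves the estimate unchanged: they fall
#' outside the kept half or outside the chosen window.
#'
#' @param set_a,set_b numeric beat-amplitude sets (peak minus preceding
#'   trough, peak minus following trough), each of length >= 2.
#' @return A list with \code{ac} and \code{min_window_variance} (the
#'   smaller of the two selected window variances, a quality feature).
#' @export
ac_from_amplitudes <- function(set_a, set_b) {
  if (length(set_a) < 2 || length(set_b) < 2)
    stop("too few beat amplitudes for AC extraction (quality error)")
  wa <- select_min_variance_mean(top_half(set_a))
  wb <- select_min_variance_mean(top_half(set_b))
  floorv <- 1e-12
  w <- 1 / (c(wa$variance, wb$variance) + floorv)
  list(ac = sum(w * c(wa$mean, wb$mean)) / sum(w),
       min_window_variance = min(wa$variance, wb$variance))
}

#' Extract the pulsatile (AC) intensity from a trace
#'
#' Forms the two beat-amplitude sets (peak minus preceding trough, peak
#' minus following trough) from the bandpassed trace and estimates the AC
#' component with \code{\link{ac_from_amplitudes}}.
#'
#' @param bandpassed zero-mean bandpassed trace.
#' @param landmarks a \code{ppg_landmarks} object for that trace.
#' @return A list with \code{ac} and \code{min_window_variance}.
#' @export
extract_ac <- function(bandpassed, landmarks) {
  if (length(landmarks$peaks) + length(landmarks$troughs) < 4)
    stop("too few landmarks for AC extraction (quality error)")
  sets <- amplitude_sets(bandpassed, landmarks)
  ac_from_amplitudes(sets$a, sets$b)
}

#' Extract the static (DC) intensity
#'
#' Takes the trough intensities from the baseline-preserving
#' (mean-filtered) trace, sorts them descending and returns the mean of
#' the minimum-variance half-length window — the most self-consistent run
#' of end-beat baseline values.
#'
#' @param mean_filtered baseline-preserving (moving-average filtered)
#'   trace.
#' @param landmarks a \code{ppg_landmarks} object located on the matching
#'   bandpassed trace.
#' @return The DC intensity (scalar).
#' @export
extract_dc <- function(mean_filtered, landmarks) {
  if (length(landmarks$troughs) < 2)
    stop("too few troughs for DC extraction (quality error)")
  v <- sort(mean_filtered[landmarks$troughs], decreasing = TRUE)
  select_min_variance_mean(v)$mean
}

#' Per-channel AC/DC feature extraction
#'
#' Runs the full single-channel chain: moving average, FIR bandpass,
#' landmark detection, then AC and DC extraction. Landmarks are detected
#' on the negated bandpassed trace so that "peaks" are systolic (maximum
#' path modulation, minimum transmitted intensity) and "troughs" the
#' diastolic baseline; the DC component is therefore read at the systolic
#' intensity minima of the mean-filtered trace, matching the Beer-Lambert
#' convention that the static path includes the full arterial diameter.
#'
#' @param x transmitted-intensity trace for one channel.
#' @param fs_hz sampling rate.
#' @param ma_window moving-average window (samples). The default of 9
#'   samples (18 ms at 500 Hz) tames sample-level noise spikes while
#'   attenuating the pulse harmonics by well under 1%; the 0.6-10 Hz
#'   bandpass that follows removes the remaining high-frequency content.
#' @param ... passed to \code{\link{detect_landmarks}}.
#' @return A list with \code{ac}, \code{dc}, \code{ratio},
#'   \code{min_window_variance}, \code{n_peaks}, \code{n_troughs}.
#' @export
extract_channel_features <- function(x, fs_hz, ma_window = 9, ...) {
  smoothed <- moving_average(x, ma_window)
  bp <- bandpass_fir(smoothed, fs_hz)
  lm <- detect_landmarks(-bp, fs_hz, ...)
  acres <- extract_ac(-bp, lm)
  # systolic landmarks of -bp are the intensity minima: DC is read there
  dc_lm <- list(troughs = lm$peaks)
  dc <- extract_dc(smoothed, dc_lm)
  if (!is.finite(dc) || dc <= 0)
    stop("non-positive DC estimate (quality error)")
  list(ac = acres$ac, dc = dc, ratio = acres$ac / dc,
       min_window_variance = acres$min_window_variance,
       n_peaks = length(lm$peaks), n_troughs = length(lm$troughs))
}

#' Extract the regression feature vector from a record
#'
#' Applies \code{\link{extract_channel_features}} to every channel and
#' assembles the per-wavelength AC/DC ratios into the model input:
#' narrowband channels in ascending wavelength order, the broadband
#' channel last, optionally followed by the mean of the pressure trace as
#' a ninth feature.
#'
#' @param rec a \code{\link{ppg_record}}.
#' @param include_pressure append the mean pressure as the final feature?
#' @param ... passed to \code{\link{extract_channel_features}}.
#' @return A list with \code{channels} (data frame of per-channel
#'   features, ordered as above) and \code{features} (named numeric
#'   vector of length 8 or 9).
#' @export
extract_features <- function(rec, include_pressure = TRUE, ...) {
  stopifnot(inherits(rec, "ppg_record"))
  k <- ncol(rec$channels)
  nb <- which(!rec$broadband)
  ord <- c(nb[order(rec$wavelengths_nm[nb])], which(rec$broadband))
  res <- vector("list", k)
  failed <- character(0)
  for (j in seq_len(k)) {
    ch <- ord[j]
    r <- tryCatch(
      extract_channel_features(rec$channels[, ch], rec$fs_hz, ...),
      error = function(e) e)
    if (inherits(r, "error")) {
      failed <- c(failed,
                  sprintf("channel %d (%g nm): %s", ch,
                          rec$wavelengths_nm[ch], conditionMessage(r)))
    } else res[[j]] <- r
  }
  if (length(failed))
    stop("quality error in record, failed channels:\n  ",
         paste(failed, collapse = "\n  "))
  chdf <- do.call(rbind, lapply(res, as.data.frame))
  chdf <- cbind(wavelength_nm = rec$wavelengths_nm[ord],
                broadband = rec$broadband[ord], chdf)
  feats <- chdf$ratio
  names(feats) <- paste0("ratio_",
                         ifelse(chdf$broadband, "broadband",
                                paste0(chdf$wavelength_nm, "nm")))
  if (include_pressure)
    feats <- c(feats, mean_pressure = mean(rec$pressure))
  list(channels = chdf, features = feats)
}
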