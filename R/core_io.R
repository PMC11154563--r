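#' Construct a multichannel PPG record
#'
#' Container for one acquisition: a uniform time grid, one transmitted
#' intensity column per LED channel, the force-sensor and displacement
#' traces collected alongside, and the acquisition metadata.
#'
#' @param time numeric vector of sample times in seconds (uniform grid).
#' @param channels numeric matrix of transmitted intensities (arbitrary ADC
#'   units), one column per LED channel.
#' @param wavelengths_nm numeric vector of nominal peak wavelengths, one per
#'   channel. For the broadband channel this is the band centre.
#' @param broadband logical vector flagging the broadband channel(s).
#' @param pressure numeric force-sensor trace (arbitrary units).
#' @param displacement numeric LED-sensor distance trace (mm).
#' @param fs_hz sampling rate in Hz (default 500).
#'
#' @return An object of class \code{ppg_record}.
#' @export
ppg_record <- function(time, channels, wavelengths_nm, broadband,
                       pressure, displacement, fs_hz = 500) {
  channels <- as.matrix(channels)
  n <- length(time)
  if (nrow(channels) != n || length(pressure) != n || length(displacement) != n)
    stop("all signal columns must have the same length")
  if (ncol(channels) != length(wavelengths_nm) ||
      ncol(channels) != length(broadband))
    stop("wavelengths_nm and broadband must have one entry per channel")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("fs_hz must be a positive scalar")
  if (any(channels < 0)) stop("intensities must be non-negative")
  if (ncol(channels) == 8L && sum(broadband) != 1L)
    stop("an 8-channel record must flag exactly one broadband channel")
  structure(
    list(time = as.numeric(time), channels = channels,
         wavelengths_nm = as.numeric(wavelengths_nm),
         broadband = as.logical(broadband),
         pressure = as.numeric(pressure),
         displacement = as.numeric(displacement),
         fs_hz = as.numeric(fs_hz)),
    class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d channels, %d samples @ %g Hz (%.1f s)\n",
              ncol(x$channels), nrow(x$channels), x$fs_hz,
              nrow(x$channels) / x$fs_hz))
  cat("  wavelengths (nm):",
      paste0(x$wavelengths_nm, ifelse(x$broadband, "*", "")), "\n")
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a PPG record to disk
#'
#' Writes a comma-separated signal file (columns \code{time},
#' \code{ch1..chK}, \code{pressure}, \code{displacement}) plus a JSON
#' metadata sidecar at \code{<path>.json} carrying the sampling rate,
#' wavelengths and broadband flag.
#'
#' @param rec a \code{\link{ppg_record}}.
#' @param path output CSV path; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
write_ppg <- function(rec, path) {
  stopifnot(inherits(rec, "ppg_record"))
  k <- ncol(rec$channels)
  df <- data.frame(time = rec$time, rec$channels,
                   pressure = rec$pressure, displacement = rec$displacement)
  names(df) <- c("time", paste0("ch", seq_len(k)), "pressure", "displacement")
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs_hz = rec$fs_hz, wavelengths_nm = rec$wavelengths_nm,
               broadband = rec$broadband)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PPG record from disk
#'
#' Inverse of \code{\link{write_ppg}}: expects a delimited signal file with a
#' header row and a JSON metadata sidecar at \code{<path>.json}.
#'
#' @param path CSV path written by \code{\link{write_ppg}} (or conforming to
#'   its layout).
#' @return A \code{\link{ppg_record}}.
#' @export
read_ppg <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON metadata sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("fs_hz", "wavelengths_nm", "broadband"))
    if (is.null(meta[[f]])) stop("sidecar missing field: ", f)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error   = function(e) stop("malformed signal file ", path, ": ",
                               conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed signal file ", path, ": ",
                               conditionMessage(w), call. = FALSE))
  need <- c("time", "pressure", "displacement")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("signal file header missing column(s): ", paste(miss, collapse = ", "))
  chcols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (!length(chcols)) stop("signal file has no channel columns (ch1, ch2, ...)")
  chcols <- chcols[order(as.integer(sub("^ch", "", chcols)))]
  if (anyNA(df)) {
    bad <- which(!stats::complete.cases(df))[1L]
    stop("non-numeric or missing cell at data line ", bad, " of ", path)
  }
  ppg_record(time = df$time,
             channels = as.matrix(df[chcols]),
             wavelengths_nm = meta$wavelengths_nm,
             broadband = meta$broadband,
             pressure = df$pressure,
             displacement = df$displacement,
             fs_hz = meta$fs_hz)
}

clinical_fields <- c("hemoglobin_g_per_L", "gender", "age", "systolic_mmHg",
                     "diastolic_mmHg", "heart_rate_bpm",
                     "creatinine_umol_per_L", "urea_mmol_per_L")

#' Load the packaged clinical subject table
#'
#' Returns the 56-subject clinical characteristics table shipped with the
#' package (hemoglobin in g/L, gender, age, blood pressure, heart rate,
#' creatinine, urea). Cells that were not collected are \code{NA}. The
#' printed blood-pressure pairs are stored with the larger (systolic) value
#' in \code{systolic_mmHg}.
#'
#' @return A data frame of class \code{clinical_table}, one row per subject,
#'   with unique integer \code{id}.
#' @export
load_clinical_fixture <- function() {
  path <- system.file("extdata", "clinical_subjects.csv", package = "ppghb",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(d$id)) stop("clinical table ids must be unique")
  if (any(d$hemoglobin_g_per_L <= 0)) stop("hemoglobin must be positive")
  class(d) <- c("clinical_table", "data.frame")
  d
}

#' Keep only subjects complete in the named fields
#'
#' @param table a clinical table (data frame as returned by
#'   \code{\link{load_clinical_fixture}}).
#' @param fields character vector of column names that must all be present
#'   (non-missing) for a record to be kept; an empty vector keeps everything.
#' @return The filtered table (same class).
#' @export
filter_complete <- function(table, fields = character()) {
  unknown <- setdiff(fields, names(table))
  if (length(unknown))
    stop("unknown field(s): ", paste(unknown, collapse = ", "))
  if (!length(fields)) return(table)
  keep <- stats::complete.cases(table[, fields, drop = FALSE])
  table[keep, , drop = FALSE]
}
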