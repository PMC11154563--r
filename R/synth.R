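# Beer-Lambert forward simulator for multiwavelength transmissive PPG.
# Transmitted intensity per narrowband channel:
#   I(t) = Is * 10^-( eps_static*L + (sum_i eps_Hb(i)*C_Hb(i)) * dL * p(t) )
# with p(t) in [0,1] the pulse path-modulation waveform; the broadband
# channel is the emission-weighted sum of narrowband responses across the
# wavelength grid.

#' Evaluate with a temporary RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default synthetic extinction table
#'
#' A deterministic per-wavelength absorption table for the four hemoglobin
#' species (oxy-, reduced, met-, carboxyhemoglobin) plus a lumped static
#' tissue term, on a 550-1100 nm grid (the overlap of a typical silicon
#' photodiode, optical bandpass filter and LED emission range). The curves
#' are synthetic smooth shapes, not literature digitizations: they reproduce
#' the qualitative ordering that matters for the method (reduced hemoglobin
#' absorbs more at 660 nm than at 940 nm; oxyhemoglobin absorption rises
#' toward 880-940 nm), and downstream correctness depends only on such
#' ordering and on monotonicity in concentration, never on absolute values.
#'
#' Units: hemoglobin coefficients are per (g/L x mm); the static term is
#' absorbance per mm of tissue path.
#'
#' @return A list of class \code{extinction_table} with \code{grid_nm},
#'   matrix \code{eps_hb} (rows = grid, columns = species) and
#'   \code{eps_static}.
#' @export
default_extinction_table <- function() {
  grid_nm <- seq(550, 1100, by = 5)
  g <- function(center, width, amp, floor_val)
    amp * exp(-0.5 * ((grid_nm - center) / width)^2) + floor_val
  eps_hb <- cbind(
    oxyhemoglobin     = g(910, 180, 0.0035, 3e-4),
    reduced           = g(640,  90, 0.0040, 4e-4),
    methemoglobin     = g(630, 150, 0.0010, 2e-4),
    carboxyhemoglobin = g(570, 100, 0.0012, 1e-4))
  eps_static <- 0.10 + 0.02 * exp(-0.5 * ((grid_nm - 980) / 80)^2)
  structure(list(grid_nm = grid_nm, eps_hb = eps_hb, eps_static = eps_static),
            class = "extinction_table")
}

#' Pulse morphology defaults
#'
#' Positions and widths are fractions of the cardiac cycle: a systolic
#' primary wave followed by a smaller diastolic sub-wave (dicrotic wave).
#'
#' @param primary_center,primary_width phase and Gaussian width of the
#'   systolic primary wave.
#' @param sub_center,sub_width phase and width of the diastolic sub-wave.
#' @param sub_amp sub-wave amplitude relative to the primary wave.
#' @return A named list of morphology parameters.
#' @export
pulse_morphology <- function(primary_center = 0.25, primary_width = 0.07,
                             sub_center = 0.55, sub_width = 0.10,
                             sub_amp = 0.35) {
  list(primary_center = primary_center, primary_width = primary_width,
       sub_center = sub_center, sub_width = sub_width, sub_amp = sub_amp)
}

periodic_gauss <- function(u, center, width) {
  exp(-0.5 * ((u - center - 1) / width)^2) +
    exp(-0.5 * ((u - center) / width)^2) +
    exp(-0.5 * ((u - center + 1) / width)^2)
}

#' Unit pulse path-modulation waveform
#'
#' Periodic waveform in [0, 1] with a systolic primary wave and a diastolic
#' sub-wave per cardiac cycle; 1 corresponds to peak arterial path
#' modulation (peak systole), 0 to end-diastole.
#'
#' @param t numeric vector of times in seconds.
#' @param heart_rate_hz cardiac frequency in Hz; must lie in (0.6, 3.0).
#' @param morphology a list as from \code{\link{pulse_morphology}}.
#' @return Numeric vector \code{p(t)} in [0, 1], attaining 0 and 1 once per
#'   period (to grid precision).
#' @export
pulse_waveform <- function(t, heart_rate_hz, morphology = pulse_morphology()) {
  if (heart_rate_hz <= 0.6 || heart_rate_hz >= 3.0)
    stop("heart_rate_hz must lie in (0.6, 3.0)")
  m <- morphology
  shape <- function(u)
    periodic_gauss(u, m$primary_center, m$primary_width) +
      m$sub_amp * periodic_gauss(u, m$sub_center, m$sub_width)
  uref <- seq(0, 1, length.out = 4096)
  sref <- shape(uref)
  lo <- min(sref); hi <- max(sref)
  u <- (t * heart_rate_hz) %% 1
  pmin(1, pmax(0, (shape(u) - lo) / (hi - lo)))
}

#' Simulation configuration
#'
#' Parameters of the Beer-Lambert forward model and of the measurement
#' imperfections layered on top of it. Contact pressure is coupled to the
#' pulsatile amplitude: the effective path modulation is
#' \code{dL_mm * (1 + pressure_gain * (pressure_mean - pressure_ref) / pressure_ref)},
#' emulating perfusion changes under varying finger force.
#'
#' @param hb_g_per_L total hemoglobin concentration (g/L).
#' @param species_fractions fractions of total hemoglobin per species, in
#'   the order of \code{\link{default_extinction_table}} columns; must sum
#'   to 1.
#' @param Is source intensity per channel (ADC units); scalar recycled.
#' @param L_mm baseline optical path through the finger (mm).
#' @param dL_mm peak arterial path modulation (mm).
#' @param heart_rate_hz cardiac frequency (Hz).
#' @param fs_hz sampling rate (Hz), 500 by default.
#' @param duration_s record length (s).
#' @param noise_sd additive Gaussian noise SD (ADC units).
#' @param drift_amp,drift_hz sinusoidal baseline drift amplitude (ADC
#'   units) and frequency; \code{drift_hz} must stay below the 0.6 Hz
#'   bandpass low edge.
#' @param artifact_rate Poisson rate of motion-artifact bursts (events/s).
#' @param pressure_mean,pressure_sd force-sensor trace mean and
#'   within-record SD (arbitrary units).
#' @param pressure_gain,pressure_ref pressure-to-amplitude coupling (see
#'   above).
#' @param displacement_mm LED-sensor distance (mm).
#' @param wavelengths_nm narrowband channel peak wavelengths (nm).
#' @param broadband_center,broadband_width centre and Gaussian width (nm) of
#'   the broadband LED emission spectrum used as integration weights.
#' @param morphology pulse morphology, see \code{\link{pulse_morphology}}.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(hb_g_per_L = 140,
                       species_fractions = c(oxyhemoglobin = 0.96,
                                             reduced = 0.02,
                                             methemoglobin = 0.01,
                                             carboxyhemoglobin = 0.01),
                       Is = 4e4, L_mm = 10, dL_mm = 0.05,
                       heart_rate_hz = 1.2, fs_hz = 500, duration_s = 12,
                       noise_sd = 2, drift_amp = 30, drift_hz = 0.15,
                       artifact_rate = 0,
                       pressure_mean = 3, pressure_sd = 0.05,
                       pressure_gain = 0.5, pressure_ref = 3,
                       displacement_mm = 12,
                       wavelengths_nm = c(660, 700, 730, 800, 850, 880, 940),
                       broadband_center = 850, broadband_width = 150,
                       morphology = pulse_morphology(), seed = NULL) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$species_fractions) - 1) > 1e-9)
    stop("species_fractions must sum to 1")
  pos <- c("hb_g_per_L", "Is", "L_mm", "heart_rate_hz", "fs_hz",
           "duration_s", "pressure_mean", "displacement_mm")
  for (f in pos) if (any(cfg[[f]] <= 0)) stop(f, " must be positive")
  nonneg <- c("dL_mm", "noise_sd", "drift_amp", "artifact_rate",
              "pressure_sd")
  for (f in nonneg) if (any(cfg[[f]] < 0)) stop(f, " must be non-negative")
  if (cfg$drift_hz >= 0.5)
    stop("drift_hz must stay below the bandpass low edge (< 0.5 Hz)")
  class(cfg) <- "sim_config"
  cfg
}

# Clean per-channel intensity as a function of the pulse waveform value p,
# vectorized over p. Returns a matrix (length(p) x n_channels), broadband
# channel last.
clean_intensity <- function(p, cfg, ext, dl_eff) {
  idx <- vapply(cfg$wavelengths_nm,
                function(w) which.min(abs(ext$grid_nm - w)), integer(1))
  eps_dyn_grid <- as.numeric(ext$eps_hb %*%
                               (cfg$species_fractions * cfg$hb_g_per_L))
  nb <- vapply(seq_along(idx), function(j) {
    i <- idx[j]
    cfg$Is * 10^-(ext$eps_static[i] * cfg$L_mm +
                    eps_dyn_grid[i] * dl_eff * p)
  }, numeric(length(p)))
  if (length(p) == 1L) nb <- matrix(nb, nrow = 1L)
  b <- exp(-0.5 * ((ext$grid_nm - cfg$broadband_center) /
                     cfg$broadband_width)^2)
  b <- b / sum(b)
  A_grid <- outer(p, eps_dyn_grid * dl_eff) +
    matrix(ext$eps_static * cfg$L_mm, nrow = length(p),
           ncol = length(ext$grid_nm), byrow = TRUE)
  bb <- as.numeric((cfg$Is * 10^-A_grid) %*% b)
  cbind(nb, bb)
}

#' Simulate one multichannel PPG record
#'
#' Evaluates the Beer-Lambert forward model per channel, forms the
#' broadband channel as the emission-spectrum-weighted sum of narrowband
#' responses over the wavelength grid, then adds baseline drift, Gaussian
#' noise and Poisson-timed motion-artifact bursts. Ground truth is computed
#' from the noise-free signal: per channel, \code{I_DC} is the over-cycle
#' minimum of clean transmitted intensity (peak systole, path L + dL) and
#' \code{I_AC} the over-cycle max minus min.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param ext an extinction table, see \code{\link{default_extinction_table}}.
#' @return A list with elements \code{record} (a \code{\link{ppg_record}},
#'   broadband channel last) and \code{truth} (data frame of per-channel
#'   \code{ac}, \code{dc}, \code{ratio}, plus attribute
#'   \code{hb_g_per_L}).
#' @export
simulate_ppg <- function(cfg = sim_config(), ext = default_extinction_table()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$fs_hz)
    t <- (seq_len(n) - 1) / cfg$fs_hz
    p <- pulse_waveform(t, cfg$heart_rate_hz, cfg$morphology)
    dl_eff <- cfg$dL_mm *
      (1 + cfg$pressure_gain *
         (cfg$pressure_mean - cfg$pressure_ref) / cfg$pressure_ref)
    clean <- clean_intensity(p, cfg, ext, dl_eff)
    ends <- clean_intensity(c(0, 1), cfg, ext, dl_eff)
    i_dc <- ends[2L, ]                    # systolic minimum (path L + dL)
    i_ac <- ends[1L, ] - ends[2L, ]
    k <- ncol(clean)
    noisy <- clean +
      cfg$drift_amp * sin(2 * pi * cfg$drift_hz * t) +
      matrix(stats::rnorm(n * k, sd = cfg$noise_sd), n, k)
    n_art <- stats::rpois(1, cfg$artifact_rate * cfg$duration_s)
    if (n_art > 0) {
      for (a in seq_len(n_art)) {
        onset <- stats::runif(1, 0, cfg$duration_s)
        dur <- stats::runif(1, 0.3, 1.0)
        amp_mult <- stats::runif(1, 1, 3) * sample(c(-1, 1), 1)
        i0 <- max(1L, round(onset * cfg$fs_hz))
        i1 <- min(n, i0 + round(dur * cfg$fs_hz))
        idx <- i0:i1
        bump <- sin(pi * seq(0, 1, length.out = length(idx)))^2
        noisy[idx, ] <- noisy[idx, ] +
          outer(bump, amp_mult * i_ac)
      }
    }
    noisy <- pmax(noisy, 0)
    if (any(!is.finite(noisy))) stop("non-finite simulated intensities")
    pressure <- cfg$pressure_mean + stats::rnorm(n, sd = cfg$pressure_sd)
    displacement <- cfg$displacement_mm + stats::rnorm(n, sd = 0.01)
    rec <- ppg_record(
      time = t, channels = noisy,
      wavelengths_nm = c(cfg$wavelengths_nm, cfg$broadband_center),
      broadband = c(rep(FALSE, k - 1L), TRUE),
      pressure = pressure, displacement = displacement, fs_hz = cfg$fs_hz)
    truth <- data.frame(
      wavelength_nm = c(cfg$wavelengths_nm, cfg$broadband_center),
      broadband = c(rep(FALSE, k - 1L), TRUE),
      ac = i_ac, dc = i_dc, ratio = i_ac / i_dc)
    attr(truth, "hb_g_per_L") <- cfg$hb_g_per_L
    list(record = rec, truth = truth)
  })
}

#' Simulate a cohort of PPG records with quality labels
#'
#' Draws per-subject hemoglobin uniformly on \code{hb_range}, heart rate
#' uniformly on \code{hr_range} and mean contact pressure from a normal
#' between-subject distribution, then simulates each record. A fixed
#' fraction of records ("poor") receives strongly elevated artifact rate
#' and noise, producing a labelled set for quality-classifier training.
#'
#' @param n number of records.
#' @param hb_range hemoglobin range (g/L), drawn uniformly.
#' @param quality_mix fraction of poor-quality records in [0, 1]; exactly
#'   \code{floor(quality_mix * n)} records are labelled poor.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param base_cfg template \code{\link{sim_config}} for shared parameters.
#' @param hr_range heart-rate range (Hz), drawn uniformly.
#' @param pressure_rel_sd between-subject relative SD of mean contact
#'   pressure.
#' @param poor_artifact_rate,poor_noise_mult artifact rate (events/s) and
#'   noise multiplier applied to poor-quality records at full severity.
#'   Each poor record draws a severity factor uniformly on [0.1, 1] that
#'   scales both, so corruption ranges from mild (hard to tell from good)
#'   to gross, keeping the classification task nontrivial.
#' @param ext extinction table shared by all records.
#' @return A list of length \code{n}; each element has \code{record},
#'   \code{truth} and \code{quality} (factor, levels
#'   \code{c("good", "poor")}).
#' @export
simulate_cohort <- function(n, hb_range = c(80, 160), quality_mix = 0,
                            seed = 1, base_cfg = sim_config(),
                            hr_range = c(1.0, 1.5), pressure_rel_sd = 0.15,
                            poor_artifact_rate = 0.3, poor_noise_mult = 3,
                            ext = default_extinction_table()) {
  if (n < 1) stop("n must be at least 1")
  if (quality_mix < 0 || quality_mix > 1) stop("quality_mix must be in [0, 1]")
  if (diff(range(hb_range)) <= 0 || length(hb_range) != 2L)
    stop("hb_range must be a nonempty (low, high) interval")
  with_seed(seed, {
    hb <- stats::runif(n, hb_range[1], hb_range[2])
    hr <- stats::runif(n, hr_range[1], hr_range[2])
    pmean <- base_cfg$pressure_ref *
      (1 + stats::rnorm(n, sd = pressure_rel_sd))
    pmean <- pmax(pmean, 0.2 * base_cfg$pressure_ref)
    n_poor <- floor(quality_mix * n)
    poor <- rep(FALSE, n)
    if (n_poor > 0) poor[sample.int(n, n_poor)] <- TRUE
    severity <- stats::runif(n, 0.1, 1)
    rec_seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      cfg <- base_cfg
      cfg$hb_g_per_L <- hb[i]
      cfg$heart_rate_hz <- hr[i]
      cfg$pressure_mean <- pmean[i]
      cfg$seed <- rec_seeds[i]
      if (poor[i]) {
        cfg$artifact_rate <- severity[i] * poor_artifact_rate
        cfg$noise_sd <- base_cfg$noise_sd *
          (1 + severity[i] * (poor_noise_mult - 1))
      }
      out <- simulate_ppg(cfg, ext)
      out$quality <- factor(if (poor[i]) "poor" else "good",
                            levels = c("good", "poor"))
      out
    })
  })
}
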