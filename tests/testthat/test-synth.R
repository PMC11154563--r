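test_that("extinction table is deterministic with the expected ordering", {
  e1 <- default_extinction_table()
  e2 <- default_extinction_table()
  expect_identical(e1, e2)
  expect_true(all(e1$eps_hb >= 0))
  expect_true(all(e1$eps_static >= 0))
  expect_true(all(diff(e1$grid_nm) > 0))
  expect_equal(range(e1$grid_nm), c(550, 1100))
  at <- function(species, nm) e1$eps_hb[e1$grid_nm == nm, species]
  expect_gt(at("reduced", 660), at("reduced", 940))
  # oxyhemoglobin rises from the red toward its NIR peak
  expect_gt(at("oxyhemoglobin", 880), at("oxyhemoglobin", 660))
})

test_that("pulse waveform is periodic with primary and sub-wave", {
  t <- seq(0, 10, by = 1 / 500)
  p <- pulse_waveform(t, 1.2)
  expect_true(all(p >= 0 & p <= 1))
  # count primary peaks: local maxima above the sub-wave amplitude
  imax <- which(diff(sign(diff(p))) < 0) + 1L
  expect_equal(sum(p[imax] > 0.5), 12)
  # with the sub-wave present there are two maxima per interior period
  expect_gte(sum(p[imax] <= 0.5), 9)

  # no sub-wave: one maximum per period
  p0 <- pulse_waveform(t, 1.0, pulse_morphology(sub_amp = 0))
  imax0 <- which(diff(sign(diff(p0))) < 0) + 1L
  expect_equal(length(imax0), 10)

  expect_error(pulse_waveform(t, 0.5), "heart_rate")
  expect_error(pulse_waveform(t, 3.5), "heart_rate")
})

test_that("noise-free simulation equals the closed-form Beer-Lambert model", {
  cfg <- sim_config(noise_sd = 0, drift_amp = 0, artifact_rate = 0,
                    duration_s = 5, seed = 7)
  ext <- default_extinction_table()
  sim <- simulate_ppg(cfg, ext)
  # independent evaluation for the 660 nm channel
  t <- sim$record$time
  p <- pulse_waveform(t, cfg$heart_rate_hz, cfg$morphology)
  i660 <- which(ext$grid_nm == 660)
  eps_dyn <- sum(ext$eps_hb[i660, ] * cfg$species_fractions) * cfg$hb_g_per_L
  expected <- cfg$Is * 10^-(ext$eps_static[i660] * cfg$L_mm +
                              eps_dyn * cfg$dL_mm * p)
  expect_equal(sim$record$channels[, 1], expected, tolerance = 1e-12)
  # ground truth ratio agrees with the analytic form
  expect_equal(sim$truth$ratio[1], 10^(eps_dyn * cfg$dL_mm) - 1,
               tolerance = 1e-12)
})

test_that("zero path modulation gives zero AC everywhere", {
  cfg <- sim_config(dL_mm = 0, noise_sd = 0, drift_amp = 0,
                    duration_s = 3, seed = 1)
  sim <- simulate_ppg(cfg)
  expect_equal(sim$truth$ac, rep(0, 8))
})

test_that("true AC/DC ratio increases with hemoglobin on every channel", {
  mk <- function(hb) simulate_ppg(sim_config(hb_g_per_L = hb, noise_sd = 0,
                                             drift_amp = 0, duration_s = 2,
                                             seed = 3))$truth$ratio
  r90 <- mk(90); r150 <- mk(150)
  expect_true(all(r150 > r90))
})

test_that("a single-line broadband spectrum degenerates to the narrowband channel", {
  cfg <- sim_config(noise_sd = 0, drift_amp = 0, duration_s = 3,
                    broadband_center = 660, broadband_width = 0.1, seed = 2)
  sim <- simulate_ppg(cfg)
  expect_equal(sim$record$channels[, 8], sim$record$channels[, 1],
               tolerance = 1e-14)
  expect_equal(sim$truth$ratio[8], sim$truth$ratio[1], tolerance = 1e-14)
})

test_that("cohort generation is reproducible with exact label counts", {
  co <- simulate_cohort(10, quality_mix = 0.3, seed = 11, base_cfg =
                          sim_config(duration_s = 2))
  expect_length(co, 10)
  expect_equal(sum(vapply(co, function(r) r$quality == "poor", logical(1))), 3)
  co2 <- simulate_cohort(10, quality_mix = 0.3, seed = 11, base_cfg =
                           sim_config(duration_s = 2))
  hb1 <- vapply(co, function(r) attr(r$truth, "hb_g_per_L"), numeric(1))
  hb2 <- vapply(co2, function(r) attr(r$truth, "hb_g_per_L"), numeric(1))
  expect_identical(hb1, hb2)
  expect_identical(co[[1]]$record$channels, co2[[1]]$record$channels)

  one <- simulate_cohort(1, seed = 4, base_cfg = sim_config(duration_s = 2))
  expect_length(one, 1)
  expect_error(simulate_cohort(5, hb_range = c(120, 120)), "interval")
  expect_error(simulate_cohort(0), "at least 1")
})
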