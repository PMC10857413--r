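test_that("recording construction validates sampling and finiteness", {
  t <- seq(0, 10, by = 0.1)
  expect_s3_class(eda_recording(t, rep(1, length(t))), "eda_recording")
  t_gap <- t; t_gap[50] <- t_gap[50] + 0.05
  expect_error(eda_recording(t_gap, rep(1, length(t))),
               class = "sampling_error")
  expect_error(eda_recording(t, c(NA, rep(1, length(t) - 1))),
               class = "data_error")
})

test_that("decomposition reconstructs the raw signal exactly", {
  for (seed in 1:5) {
    prof <- sample_subject(default_population(), seed = seed)
    rec <- simulate_eda(prof, short_schedule(),
                        sim_config(fs_eda_hz = 20), seed = seed)
    dec <- decompose_eda(rec)
    expect_lt(max(abs(dec$phasic_uS + dec$tonic_uS - rec$eda_uS)), 1e-9)
  }
})

test_that("a constant trace is all tonic (DC rejection)", {
  t <- seq(0, 400, by = 0.05)
  dec <- decompose_eda(eda_recording(t, rep(5, length(t))))
  inner <- t > 50 & t < 350
  expect_lt(max(abs(dec$phasic_uS[inner])), 1e-3)
  expect_equal(mean(dec$tonic_uS[inner]), 5, tolerance = 1e-3)
})

test_that("filter response matches the analytic Butterworth magnitude", {
  t <- seq(0, 600, by = 0.02)
  # pass band: 0.5 Hz is 10x the cutoff
  rec <- eda_recording(t, 5 + sin(2 * pi * 0.5 * t))
  dec <- decompose_eda(rec, fc_hz = 0.05)
  inner <- t > 100 & t < 500
  amp <- fit_sine_amplitude(t[inner], dec$phasic_uS[inner], 0.5)
  expect_gte(amp, 0.95)
  expect_lt(abs(amp - oracle_filtfilt_hp_mag(0.5, 0.05)), 0.01)

  # stop band: 0.005 Hz is a tenth of the cutoff
  rec2 <- eda_recording(t, 5 + sin(2 * pi * 0.005 * t))
  dec2 <- decompose_eda(rec2, fc_hz = 0.05)
  amp2 <- fit_sine_amplitude(t[inner], dec2$phasic_uS[inner], 0.005)
  expect_lte(amp2, oracle_filtfilt_hp_mag(0.005, 0.05) + 0.01)
})

test_that("too-short or invalid recordings are rejected", {
  t <- seq(0, 50, by = 0.05)
  expect_error(decompose_eda(eda_recording(t, rnorm(length(t)) + 5)),
               class = "length_error")
})

test_that("injected kernels are recovered exactly (count, times, amplitudes)", {
  t <- seq(0, 120, by = 0.02)
  times <- c(10, 30, 50); amps <- c(0.2, 0.5, 1.0)
  dec <- kernel_decomposition(t, times, amps)
  epoch <- c(0, 120)
  ev <- detect_scrs(dec, epoch, smooth_s = 0)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$amplitude_uS, amps, tolerance = 0.05)
  # peak times: the kernel peak lags the event onset by ~1.54 s
  expect_equal(ev$peak_s, times + 1.5445, tolerance = 0.1)
  # exhaustive extremum-scan oracle agrees exactly
  osc <- oracle_scan_events(dec$time_s, dec$phasic_uS, epoch, 0.01, 1)
  expect_equal(nrow(osc), 3)
  expect_equal(ev$peak_s, osc$peak_s)
  expect_equal(ev$amplitude_uS, osc$amplitude_uS)
})

test_that("detector equals the scan oracle on random well-separated trains", {
  t <- seq(0, 300, by = 0.02)
  for (seed in 1:8) {
    set.seed(seed)
    nev <- sample(1:10, 1)
    times <- 20 + (seq_len(nev) - 1) * 25 + runif(nev, 0, 4)
    amps <- runif(nev, 0.3, 1.5)
    dec <- kernel_decomposition(t, times, amps)
    epoch <- c(0, 300)
    ev <- detect_scrs(dec, epoch, smooth_s = 0)
    osc <- oracle_scan_events(dec$time_s, dec$phasic_uS, epoch, 0.01, 1)
    expect_equal(nrow(ev), nev)
    expect_equal(ev$peak_s, osc$peak_s)
    expect_equal(ev$amplitude_uS, osc$amplitude_uS)
    expect_equal(ev$amplitude_uS, amps, tolerance = 0.05)
  }
})

test_that("near-coincident peaks merge, keeping the larger", {
  t <- seq(0, 60, by = 0.01)
  dec <- kernel_decomposition(t, c(20, 20.3), c(0.3, 0.6))
  ev <- detect_scrs(dec, c(0, 60), min_separation_s = 1, smooth_s = 0)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$amplitude_uS, 0.5)
})

test_that("an identically flat phasic yields no events", {
  t <- seq(0, 300, by = 0.02)
  dec <- decompose_eda(eda_recording(t, rep(2, length(t))))
  ev <- detect_scrs(dec, c(100, 200))
  expect_equal(nrow(ev), 0)
  expect_error(detect_scrs(dec, c(250, 400)), class = "bounds_error")
})

test_that("raising the threshold never increases the SCR count", {
  prof <- sample_subject(default_population(), seed = 31)
  rec <- simulate_eda(prof, short_schedule(), sim_config(fs_eda_hz = 25),
                      seed = 31)
  dec <- decompose_eda(rec)
  sch <- short_schedule()
  ep_on <- pressure_epochs_of(sch)[3]
  counts <- vapply(c(0.005, 0.01, 0.05, 0.1, 0.3),
                   function(th) nrow(detect_scrs(dec, c(ep_on, ep_on + 60),
                                                 threshold_uS = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("feature extraction does direct mean arithmetic", {
  prof <- quiet_profile(scl_baseline_uS = 4)
  sch <- short_schedule(epoch_duration_s = 60, pressures = 10)
  ep_on <- pressure_epochs_of(sch)[1]
  cfg <- noise_free_config(fs_eda_hz = 20)

  # constant tonic, no events -> (0, 0, 0)
  rec0 <- simulate_eda(prof, sch, cfg, seed = 1)
  f0 <- extract_eda_features(decompose_eda(rec0), c(ep_on, ep_on + 60),
                             c(ep_on - 10, ep_on))
  expect_equal(f0$mean_scl_uS, 0, tolerance = 1e-9)
  expect_equal(f0$max_scr_amp_uS, 0)
  expect_equal(f0$scr_count, 0)

  # +0.4 uS tonic step during the epoch -> mean SCL = 0.4 (pure arithmetic)
  t <- seq(0, 300, by = 0.05)
  dec_step <- kernel_decomposition(t, numeric(0), numeric(0),
                                   tonic = 4 + 0.4 * (t >= 100 & t < 200))
  f <- extract_eda_features(dec_step, c(100, 200), c(90, 100))
  expect_equal(f$mean_scl_uS, 0.4, tolerance = 1e-9)

  # and through the filter on a long epoch: a baseline window placed clear
  # of the zero-phase filter's acausal edge transient recovers the step to
  # a few percent
  prof2 <- quiet_profile(scl_baseline_uS = 4, tonic_gain_uS_per_kPa = 0.04)
  sch2 <- stimulus_schedule(data.frame(onset_s = 300, duration_s = 300,
                                       pressure_kPa = 10), span_s = 900)
  rec <- simulate_eda(prof2, sch2, cfg, seed = 1)
  ff <- extract_eda_features(decompose_eda(rec), c(300, 600), c(260, 270))
  expect_equal(ff$mean_scl_uS, 0.4, tolerance = 0.025)

  # baseline must precede the epoch
  expect_error(extract_eda_features(dec_step, c(100, 200), c(105, 115)),
               class = "bounds_error")
})

test_that("decimated processing agrees with full-rate processing", {
  prof <- sample_subject(default_population(), seed = 77)
  sch <- short_schedule()
  rec <- simulate_eda(prof, sch, sim_config(fs_eda_hz = 200,
                                            eda_noise_sd_uS = 0), seed = 77)
  ep_on <- pressure_epochs_of(sch)[2]
  epoch <- c(ep_on, ep_on + 60); base <- c(ep_on - 10, ep_on)
  f_full <- extract_eda_features(decompose_eda(rec), epoch, base)
  f_dec <- extract_eda_features(decompose_eda(rec, decimate_to_hz = 20),
                                epoch, base)
  expect_equal(f_dec$scr_count, f_full$scr_count)
  expect_equal(f_dec$max_scr_amp_uS, f_full$max_scr_amp_uS, tolerance = 0.01)
  expect_equal(f_dec$mean_scl_uS, f_full$mean_scl_uS, tolerance = 0.01)
})
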