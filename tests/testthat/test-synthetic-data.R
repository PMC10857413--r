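test_that("subject sampling is deterministic and respects dispersion", {
  pop <- default_population()

  pop0 <- pop
  pop0$dispersion <- 0
  prof <- sample_subject(pop0, seed = 5)
  for (i in seq_len(nrow(pop0)))
    expect_equal(prof[[pop0$field[i]]], pop0$mean[i])

  expect_equal(sample_subject(pop, seed = 11), sample_subject(pop, seed = 11))
  expect_false(identical(sample_subject(pop, seed = 11),
                         sample_subject(pop, seed = 12)))

  pop_bad <- pop
  pop_bad$dispersion[1] <- -0.1
  expect_error(sample_subject(pop_bad, seed = 1), class = "parameter_error")
})

test_that("sampled SCR amplitude medians match the population mean (Monte Carlo)", {
  pop <- default_population()
  row <- pop[pop$field == "scr_amp_median_uS", ]
  n <- 10000
  draws <- vapply(seq_len(n), function(i)
    sample_subject(pop, seed = 100000 + i)$scr_amp_median_uS, numeric(1))
  se <- row$mean * row$dispersion / sqrt(n)
  expect_lt(abs(mean(draws) - row$mean), 3 * se)
})

test_that("a silent subject yields a constant trace at baseline", {
  prof <- quiet_profile(scl_baseline_uS = 6.5)
  rec <- simulate_eda(prof, short_schedule(), noise_free_config(fs_eda_hz = 25),
                      seed = 1)
  expect_equal(rec$eda_uS, rep(6.5, length(rec$eda_uS)))
})

test_that("SCR event counts follow the inhomogeneous Poisson rate", {
  # lambda = 6/min over a 2-min epoch; 500 seeded replicates
  prof <- quiet_profile(scr_rate_base_per_min = 0)
  prof$scr_rate_gain_per_kPa <- 0.6 # 6/min at 10 kPa
  sch <- short_schedule(epoch_duration_s = 120, pressures = 10)
  cfg <- noise_free_config(fs_eda_hz = 5)
  lambda_t <- 6 * 2
  counts <- vapply(1:500, function(r) {
    ev <- simulate_eda(prof, sch, cfg, seed = 2000 + r)$scr_events
    sum(ev$pressure_kPa == 10)
  }, numeric(1))
  se <- sqrt(lambda_t / 500)
  expect_lt(abs(mean(counts) - lambda_t), 3 * se)
})

test_that("a forced SCR of amplitude 1 produces a unit-peak excursion", {
  prof <- quiet_profile(scl_baseline_uS = 5)
  rec <- simulate_eda(prof, short_schedule(), noise_free_config(fs_eda_hz = 1000),
                      seed = 1,
                      scr_events = data.frame(time_s = 100, amplitude_uS = 1))
  expect_equal(max(rec$eda_uS) - 5, 1, tolerance = 1e-6)
})

test_that("the Bateman kernel is unit-peak and causal", {
  tt <- seq(-5, 60, by = 1e-3)
  k <- scr_kernel(tt)
  expect_equal(max(k), 1, tolerance = 1e-8)
  expect_true(all(k[tt < 0] == 0))
  expect_error(scr_kernel(1, tau_rise_s = 4, tau_decay_s = 0.75),
               class = "parameter_error")
})

test_that("latent StO2 is constant without epochs and plateaus above occlusion", {
  cfg <- noise_free_config(sto2_drop_exponent = 1, occlusion_residual = 0)
  prof <- subject_profile(sto2_baseline_pct = 70, sto2_drop_max_pct = 60,
                          sto2_tau_s = 10)
  empty <- stimulus_schedule(data.frame(onset_s = numeric(0),
                                        duration_s = numeric(0),
                                        pressure_kPa = numeric(0)),
                             span_s = 300)
  rec <- simulate_nirs(prof, empty, cfg, seed = 1)
  expect_equal(compute_sto2(rec)$sto2_pct, rep(70, length(rec$time_s)))

  # hard plateau: P = P_occ and P = 1.5 P_occ share the same asymptote
  expect_equal(sto2_asymptote(20, prof, cfg), sto2_asymptote(30, prof, cfg))
  # strictly decreasing below occlusion
  below <- sto2_asymptote(c(5, 10, 15, 20), prof, cfg)
  expect_true(all(diff(below) < 0))

  # closed-form asymptote: 70 - 60 * (10/20) = 40 after a long epoch
  sch <- protocol_schedule(600, 10, lead_in_s = 60, anchor_onset_s = 10)
  s <- compute_sto2(simulate_nirs(prof, sch, cfg, seed = 1))
  terminal <- s$sto2_pct[max(which(s$time_s < 660))]
  expect_equal(terminal, 40, tolerance = 1e-6)
})

test_that("oxy + deoxy conserve total hemoglobin and StO2 round-trips", {
  cfg <- noise_free_config()
  prof <- subject_profile()
  rec <- simulate_nirs(prof, protocol_schedule(300), cfg, seed = 3)
  expect_equal(rec$oxyHb_au + rec$deoxyHb_au,
               rep(cfg$total_hb_au, length(rec$time_s)))
  s <- compute_sto2(rec)
  expect_true(all(s$valid_mask))
  expect_lt(max(abs(s$sto2_pct - rec$sto2_true_pct)), 1e-9)
})

test_that("VAS ratings clip at the scale ceiling and grow with pressure", {
  prof <- quiet_profile(vas_sensitivity = 1)
  sch <- short_schedule()
  v <- simulate_vas(prof, sch, seed = 1, noise_sd = 0)
  expect_equal(v$anchor$vas_raw, 10) # 1 * 60/6 clipped to 10
  r <- v$ratings[order(v$ratings$pressure_kPa), ]
  expect_true(all(diff(r$vas_raw) > 0))
  expect_equal(r$vas_raw, r$pressure_kPa / 6)
})

test_that("VAS Monte-Carlo mean matches the clipped-normal closed form", {
  prof <- quiet_profile(vas_sensitivity = 2.5) # mean 8.33 at 20 kPa: clipping bites
  sch <- short_schedule(pressures = 20)
  draws <- vapply(1:1000, function(r)
    simulate_vas(prof, sch, seed = 3000 + r, noise_sd = 0.5)$ratings$vas_raw,
    numeric(1))
  mu <- 2.5 * 20 / 6
  expected <- oracle_clipped_normal_mean(mu, 0.5)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("simulate_cohort writes the documented layout, reproducibly", {
  dir1 <- file.path(tempdir(), "coh1"); dir2 <- file.path(tempdir(), "coh2")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE), add = TRUE)
  design <- mini_design(n_subjects = 13, fs_eda_hz = 10)
  simulate_cohort(design, seed = 9, dir = dir1)
  simulate_cohort(design, seed = 9, dir = dir2)

  subdirs <- list.dirs(dir1, recursive = FALSE)
  expect_length(subdirs, 13)
  ev <- read.delim(file.path(subdirs[1], "events.tsv"), comment.char = "#")
  expect_equal(sum(ev$label == "pressure"), 3)
  expect_equal(sum(ev$label == "anchor"), 1)

  expect_identical(readLines(file.path(dir1, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))
  # collision protection
  expect_error(simulate_cohort(design, seed = 9, dir = dir1),
               class = "io_error")
})

test_that("cohorts are pure functions of (design, seed)", {
  design <- mini_design()
  c1 <- simulate_cohort(design, seed = 4)
  c2 <- simulate_cohort(design, seed = 4)
  expect_equal(c1, c2)
  c3 <- simulate_cohort(design, seed = 5)
  expect_false(identical(c1$subjects[[1]]$eda$eda_uS,
                         c3$subjects[[1]]$eda$eda_uS))
})

test_that("condition order is permuted per subject when randomized", {
  design <- mini_design(n_subjects = 12, fs_eda_hz = 5)
  coh <- simulate_cohort(design, seed = 21)
  orders <- vapply(coh$subjects, function(s) {
    ep <- s$schedule$epochs
    paste(ep$pressure_kPa[ep$label == "pressure"], collapse = "-")
  }, character(1))
  expect_gt(length(unique(orders)), 1)
})

test_that("cohort-mean SCR counts order with pressure across seeds", {
  # 20 seeded mini replicates of the 1-min design
  ok <- vapply(1:20, function(r) {
    coh <- simulate_cohort(cohort_design(
      n_subjects = 13, epoch_duration_s = 60,
      sim_config = sim_config(fs_eda_hz = 25)), seed = 400 + r)
    tab <- build_feature_table(coh)
    m <- tapply(tab$scr_count, tab$pressure_kPa, mean)
    m[["10"]] < m[["20"]] && m[["20"]] < m[["30"]]
  }, logical(1))
  expect_gte(sum(ok), 18)
})
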