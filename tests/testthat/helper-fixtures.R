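# Shared fixtures, built in code.

# a subject that emits nothing unless told to
quiet_profile <- function(...) {
  args <- utils::modifyList(
    list(scr_rate_base_per_min = 0, scr_rate_gain_per_kPa = 0,
         scl_drift_uS_per_s = 0, tonic_gain_uS_per_kPa = 0),
    list(...))
  do.call(subject_profile, args)
}

noise_free_config <- function(fs_eda_hz = 100, ...) {
  sim_config(fs_eda_hz = fs_eda_hz, eda_noise_sd_uS = 0,
             nirs_noise_sd_au = 0, vas_noise_sd = 0, ...)
}

# short schedule for fast EDA tests (span >= 10/fc = 200 s for fc = 0.05)
short_schedule <- function(epoch_duration_s = 60, pressures = c(10, 20, 30),
                           rest_s = 60, lead_in_s = 60) {
  sch <- protocol_schedule(epoch_duration_s, pressures, rest_s = rest_s,
                           lead_in_s = lead_in_s, anchor_onset_s = 10)
  sch$span_s <- max(sch$span_s, 320)
  sch
}

# an eda_decomposition whose phasic is a pure sum of Bateman kernels,
# bypassing the filter (the detector contract is about the extremum scan)
kernel_decomposition <- function(t, times, amps, tonic = 0) {
  phasic <- numeric(length(t))
  for (i in seq_along(times))
    phasic <- phasic + amps[i] * scr_kernel(t - times[i])
  tonic <- rep_len(tonic, length(t))
  structure(list(time_s = t, raw_uS = phasic + tonic, phasic_uS = phasic,
                 tonic_uS = tonic,
                 fs_hz = 1 / (t[2] - t[1]), fc_hz = 0.05,
                 filter_descriptor = "synthetic (kernel sum)"),
            class = "eda_decomposition")
}

# small fast cohort design
mini_design <- function(n_subjects = 3, epoch_duration_s = 60,
                        fs_eda_hz = 25, with_nirs = FALSE, ...) {
  cohort_design(n_subjects = n_subjects, epoch_duration_s = epoch_duration_s,
                with_nirs = with_nirs,
                sim_config = sim_config(fs_eda_hz = fs_eda_hz), ...)
}

# onsets of the pressure epochs of a schedule
pressure_epochs_of <- function(schedule) {
  ep <- schedule$epochs
  ep$onset_s[ep$label == "pressure"]
}

# build an StO2 series directly from a saturation trajectory
sto2_series_from <- function(time_s, sto2_pct) {
  compute_sto2(nirs_recording(time_s, oxyHb_au = sto2_pct,
                              deoxyHb_au = 100 - sto2_pct))
}

# random balanced long table for the statistics oracles
random_feature_table <- function(n, k = 3, seed) {
  set.seed(seed)
  data.frame(
    subject = rep(sprintf("S%02d", 1:n), each = k),
    pressure_kPa = rep(seq_len(k) * 10, n),
    value = rnorm(n * k, mean = rep(rnorm(n, 0, 2), each = k), sd = 1)
  )
}
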