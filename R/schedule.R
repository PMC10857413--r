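#' Construct a stimulus schedule
#'
#' A schedule is an ordered set of non-overlapping pressure epochs, each a
#' half-open interval `[onset_s, onset_s + duration_s)` at a constant cuff
#' pressure. The anchor epoch (used for VAS normalization) is an ordinary
#' epoch labelled `"anchor"`; feature extraction only uses epochs labelled
#' `"pressure"`.
#'
#' @param epochs data.frame with columns `onset_s`, `duration_s`,
#'   `pressure_kPa` and optionally `label` (defaults to `"pressure"`).
#' @param rest_s inter-epoch rest duration bookkeeping (s); used when
#'   building protocol schedules and recorded for provenance.
#' @param anchor_pressure_kPa normalization anchor pressure (kPa).
#' @param anchor_duration_s anchor application duration (s).
#' @param span_s total recording span (s); defaults to 60 s past the last
#'   epoch offset.
#' @return an object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(epochs, rest_s = 300,
                              anchor_pressure_kPa = 60,
                              anchor_duration_s = 5,
                              span_s = NULL) {
  if (!is.data.frame(epochs) ||
      !all(c("onset_s", "duration_s", "pressure_kPa") %in% names(epochs)))
    stopf("schedule_error",
          "epochs must have columns onset_s, duration_s, pressure_kPa")
  if (nrow(epochs) > 0) {
    if (any(!is.finite(epochs$onset_s)) || any(!is.finite(epochs$duration_s)))
      stopf("schedule_error", "non-finite epoch times")
    if (any(epochs$duration_s <= 0))
      stopf("schedule_error", "epoch durations must be positive")
    if (any(epochs$pressure_kPa <= 0))
      stopf("schedule_error", "epoch pressures must be positive")
    if (is.unsorted(epochs$onset_s, strictly = TRUE))
      stopf("schedule_error", "epoch onsets must be strictly increasing")
    off <- epochs$onset_s + epochs$duration_s
    if (nrow(epochs) > 1 && any(off[-nrow(epochs)] > epochs$onset_s[-1] + 1e-9))
      stopf("schedule_error", "epochs overlap")
  }
  if (is.null(epochs$label)) epochs$label <- rep("pressure", nrow(epochs))
  epochs$label <- as.character(epochs$label)
  if (is.null(span_s))
    span_s <- if (nrow(epochs)) max(epochs$onset_s + epochs$duration_s) + 60 else 300
  structure(list(
    epochs = epochs[, c("onset_s", "duration_s", "pressure_kPa", "label")],
    rest_s = assert_number(rest_s, "rest_s", lower = 0),
    anchor_pressure_kPa = assert_number(anchor_pressure_kPa, "anchor_pressure_kPa", lower = 1e-9),
    anchor_duration_s = assert_number(anchor_duration_s, "anchor_duration_s", lower = 1e-9),
    span_s = assert_number(span_s, "span_s", lower = 1e-9)
  ), class = "stimulus_schedule")
}

#' Build the cuff-pressure protocol schedule for one subject
#'
#' Encodes the two experimental designs: a brief anchor application (60 kPa,
#' 5 s, during the lead-in) for VAS normalization, followed by the pressure
#' epochs (1-min or 5-min, one per pressure) separated by 5-min rests.
#'
#' @param epoch_duration_s pressure-epoch duration: 60 (design 1) or 300
#'   (design 2); any positive value is accepted.
#' @param pressures_kPa pressures in *presentation order* (permute upstream
#'   for randomized order).
#' @param rest_s rest duration between pressure epochs (s).
#' @param lead_in_s quiet lead-in before the first pressure epoch (s); must
#'   leave room for the anchor and a pre-epoch baseline.
#' @param anchor_onset_s onset of the anchor application within the lead-in.
#' @inheritParams stimulus_schedule
#' @return a [stimulus_schedule()].
#' @examples
#' sch <- protocol_schedule(60, c(20, 10, 30))
#' sch$epochs
#' @export
protocol_schedule <- function(epoch_duration_s = 60,
                              pressures_kPa = c(10, 20, 30),
                              rest_s = 300,
                              lead_in_s = 120,
                              anchor_onset_s = 30,
                              anchor_pressure_kPa = 60,
                              anchor_duration_s = 5) {
  assert_number(epoch_duration_s, "epoch_duration_s", lower = 1e-9)
  assert_number(lead_in_s, "lead_in_s", lower = anchor_onset_s + anchor_duration_s + 30)
  if (length(pressures_kPa) < 1 || any(pressures_kPa <= 0) ||
      anyDuplicated(pressures_kPa))
    stopf("schedule_error", "pressures must be distinct and positive")
  k <- length(pressures_kPa)
  onsets <- lead_in_s + (seq_len(k) - 1) * (epoch_duration_s + rest_s)
  epochs <- rbind(
    data.frame(onset_s = anchor_onset_s, duration_s = anchor_duration_s,
               pressure_kPa = anchor_pressure_kPa, label = "anchor"),
    data.frame(onset_s = onsets, duration_s = epoch_duration_s,
               pressure_kPa = as.numeric(pressures_kPa), label = "pressure")
  )
  stimulus_schedule(epochs, rest_s = rest_s,
                    anchor_pressure_kPa = anchor_pressure_kPa,
                    anchor_duration_s = anchor_duration_s)
}

#' Simulation configuration
#'
#' Sampling rates, noise levels, the SCR kernel time constants and the
#' StO2 occlusion rule shared by all subjects of a simulated cohort.
#'
#' The StO2 asymptote at pressure P is
#' `S_inf(P) = baseline - drop_max * f(P)` with
#' `f(P) = (min(P, P_occ)/P_occ)^sto2_drop_exponent +
#'  occlusion_residual * max(P - P_occ, 0)/P_occ`.
#' With `sto2_drop_exponent = 1` and `occlusion_residual = 0` this is the
#' piecewise-linear hard-plateau rule; the defaults (2.3, 0.09) give the
#' convex response and slight residual decline above occlusion seen in
#' thigh-cuff data.
#'
#' @param fs_eda_hz EDA sampling rate (Hz; instrument default 1000).
#' @param fs_nirs_hz NIRS sampling rate (Hz; instrument default 5).
#' @param eda_noise_sd_uS additive Gaussian EDA measurement noise (uS).
#' @param nirs_noise_sd_au additive Gaussian noise on each hemoglobin
#'   channel (arbitrary concentration units).
#' @param scr_tau_rise_s Bateman kernel rise constant (s).
#' @param scr_tau_decay_s Bateman kernel decay constant (s; must exceed the
#'   rise constant).
#' @param scr_amp_sdlog lognormal log-SD of SCR amplitudes.
#' @param total_hb_au constant total hemoglobin (oxy + deoxy).
#' @param occlusion_pressure_kPa vascular-occlusion threshold pressure P_occ.
#' @param sto2_drop_exponent shape exponent of the drop fraction below P_occ.
#' @param occlusion_residual residual drop slope above P_occ (fraction of
#'   `sto2_drop_max_pct` per P_occ of excess pressure).
#' @param vas_noise_sd SD of the rating noise on the 0-10 VAS scale.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(fs_eda_hz = 1000,
                       fs_nirs_hz = 5,
                       eda_noise_sd_uS = 0.005,
                       nirs_noise_sd_au = 0.3,
                       scr_tau_rise_s = 0.75,
                       scr_tau_decay_s = 4,
                       scr_amp_sdlog = 0.65,
                       total_hb_au = 100,
                       occlusion_pressure_kPa = 20,
                       sto2_drop_exponent = 2.3,
                       occlusion_residual = 0.09,
                       vas_noise_sd = 0.5) {
  cfg <- list(
    fs_eda_hz = assert_number(fs_eda_hz, "fs_eda_hz", lower = 1e-9),
    fs_nirs_hz = assert_number(fs_nirs_hz, "fs_nirs_hz", lower = 1e-9),
    eda_noise_sd_uS = assert_number(eda_noise_sd_uS, "eda_noise_sd_uS", lower = 0),
    nirs_noise_sd_au = assert_number(nirs_noise_sd_au, "nirs_noise_sd_au", lower = 0),
    scr_tau_rise_s = assert_number(scr_tau_rise_s, "scr_tau_rise_s", lower = 1e-9),
    scr_tau_decay_s = assert_number(scr_tau_decay_s, "scr_tau_decay_s", lower = 1e-9),
    scr_amp_sdlog = assert_number(scr_amp_sdlog, "scr_amp_sdlog", lower = 0),
    total_hb_au = assert_number(total_hb_au, "total_hb_au", lower = 1e-9),
    occlusion_pressure_kPa = assert_number(occlusion_pressure_kPa, "occlusion_pressure_kPa", lower = 1e-9),
    sto2_drop_exponent = assert_number(sto2_drop_exponent, "sto2_drop_exponent", lower = 1e-9),
    occlusion_residual = assert_number(occlusion_residual, "occlusion_residual", lower = 0),
    vas_noise_sd = assert_number(vas_noise_sd, "vas_noise_sd", lower = 0)
  )
  if (cfg$scr_tau_decay_s <= cfg$scr_tau_rise_s)
    stopf("parameter_error", "scr_tau_decay_s must exceed scr_tau_rise_s")
  structure(cfg, class = "sim_config")
}

#' Cohort design
#'
#' The experimental design of a simulated cohort: number of subjects, epoch
#' duration (60 s for the EDA-only design, 300 s for the EDA+NIRS design),
#' the pressure set, and whether the presentation order is permuted
#' independently per subject.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param epoch_duration_s pressure-epoch duration in seconds.
#' @param pressures_kPa distinct positive pressures (kPa).
#' @param randomize_order permute condition order per subject?
#' @param with_nirs simulate the NIRS channel? Defaults to TRUE for 5-min
#'   epochs (design 2), FALSE otherwise (design 1 measured EDA only).
#' @param population population parameter table ([default_population()]).
#' @param sim_config a [sim_config()].
#' @param rest_s,lead_in_s schedule timing (see [protocol_schedule()]).
#' @return an object of class `cohort_design`.
#' @examples
#' design_exp1 <- cohort_design(n_subjects = 13, epoch_duration_s = 60)
#' design_exp2 <- cohort_design(n_subjects = 10, epoch_duration_s = 300)
#' @export
cohort_design <- function(n_subjects,
                          epoch_duration_s = 300,
                          pressures_kPa = c(10, 20, 30),
                          randomize_order = TRUE,
                          with_nirs = epoch_duration_s >= 300,
                          population = default_population(),
                          sim_config = cuffcomfort::sim_config(),
                          rest_s = 300,
                          lead_in_s = 120) {
  assert_number(n_subjects, "n_subjects", lower = 2)
  assert_number(epoch_duration_s, "epoch_duration_s", lower = 1e-9)
  if (length(pressures_kPa) < 2 || any(pressures_kPa <= 0) ||
      anyDuplicated(pressures_kPa))
    stopf("parameter_error", "pressures must be distinct and positive")
  assert_flag(randomize_order, "randomize_order")
  assert_flag(with_nirs, "with_nirs")
  if (!inherits(sim_config, "sim_config"))
    stopf("parameter_error", "sim_config must be a sim_config object")
  structure(list(
    n_subjects = as.integer(n_subjects),
    epoch_duration_s = epoch_duration_s,
    pressures_kPa = sort(as.numeric(pressures_kPa)),
    randomize_order = randomize_order,
    with_nirs = with_nirs,
    population = population,
    sim_config = sim_config,
    rest_s = rest_s,
    lead_in_s = lead_in_s
  ), class = "cohort_design")
}

# internal: pressure epochs only, as a data.frame
pressure_epochs <- function(schedule) {
  e <- schedule$epochs
  e[e$label == "pressure", , drop = FALSE]
}
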