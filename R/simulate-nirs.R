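#' Asymptotic StO2 under sustained cuff pressure
#'
#' The latent tissue-oxygen-saturation asymptote for a sustained pressure P:
#' `S_inf(P) = baseline - drop_max * f(P)` with drop fraction
#' `f(P) = (min(P, P_occ)/P_occ)^gamma + residual * max(P - P_occ, 0)/P_occ`.
#' Below the occlusion pressure the decline steepens with pressure
#' (convex for `gamma > 1`); above it the vessels are already occluded and
#' only the small residual slope remains. `gamma = 1`, `residual = 0`
#' recovers the piecewise-linear hard-plateau rule.
#'
#' @param pressure_kPa applied pressure(s).
#' @param profile a [subject_profile()].
#' @param config a [sim_config()].
#' @return asymptotic saturation(s) in percent, floored at 0.
#' @examples
#' sto2_asymptote(c(10, 20, 30), subject_profile(), sim_config())
#' @export
sto2_asymptote <- function(pressure_kPa, profile, config = sim_config()) {
  pocc <- config$occlusion_pressure_kPa
  frac <- (pmin(pressure_kPa, pocc) / pocc)^config$sto2_drop_exponent +
    config$occlusion_residual * pmax(pressure_kPa - pocc, 0) / pocc
  pmax(profile$sto2_baseline_pct - profile$sto2_drop_max_pct * frac, 0)
}

# internal: latent StO2 trajectory sampled at times t (piecewise exponential
# relaxation toward the segment target, continuous across boundaries)
latent_sto2 <- function(t, profile, schedule, config) {
  ep <- schedule$epochs
  bounds <- sort(unique(c(0, ep$onset_s, ep$onset_s + ep$duration_s,
                          schedule$span_s)))
  s <- numeric(length(t))
  s0 <- profile$sto2_baseline_pct
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    inside <- which(ep$onset_s <= t0 & ep$onset_s + ep$duration_s >= t1)
    target <- if (length(inside))
      sto2_asymptote(ep$pressure_kPa[inside[1L]], profile, config)
    else
      profile$sto2_baseline_pct
    sel <- t >= t0 & t < t1
    if (i == length(bounds) - 1L) sel <- sel | t == t1
    s[sel] <- target + (s0 - target) * exp(-(t[sel] - t0) / profile$sto2_tau_s)
    s0 <- target + (s0 - target) * exp(-(t1 - t0) / profile$sto2_tau_s)
  }
  s
}

#' Simulate a NIRS recording
#'
#' The latent StO2 trajectory relaxes exponentially (time constant
#' `sto2_tau_s`) toward the pressure-dependent asymptote
#' [sto2_asymptote()] during each epoch and back toward baseline during
#' rests. Channels are `oxyHb = THb * StO2/100` and
#' `deoxyHb = THb - oxyHb` (exact conservation before noise), each plus
#' independent Gaussian noise.
#'
#' @inheritParams simulate_eda
#' @return a [nirs_recording()] with an extra element `sto2_true_pct`, the
#'   latent trajectory.
#' @examples
#' rec <- simulate_nirs(subject_profile(), protocol_schedule(300),
#'                      sim_config(nirs_noise_sd_au = 0), seed = 1)
#' @export
simulate_nirs <- function(profile, schedule, config = sim_config(), seed = 1) {
  if (!inherits(profile, "subject_profile"))
    stopf("parameter_error", "profile must be a subject_profile")
  if (!inherits(schedule, "stimulus_schedule"))
    stopf("parameter_error", "schedule must be a stimulus_schedule")
  fs <- config$fs_nirs_hz
  n <- floor(schedule$span_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  s <- latent_sto2(t, profile, schedule, config)
  thb <- config$total_hb_au
  oxy <- thb * s / 100
  deoxy <- thb - oxy
  if (config$nirs_noise_sd_au > 0) {
    set.seed(substream_seed(seed, 0L, 3L))
    oxy <- oxy + rnorm(n, 0, config$nirs_noise_sd_au)
    deoxy <- deoxy + rnorm(n, 0, config$nirs_noise_sd_au)
  }
  rec <- nirs_recording(time_s = t, oxyHb_au = oxy, deoxyHb_au = deoxy,
                        fs_hz = fs)
  rec$sto2_true_pct <- s
  rec
}
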