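#' Unit-peak Bateman kernel
#'
#' The canonical SCR shape: a difference of exponentials
#' `exp(-t/tau_decay) - exp(-t/tau_rise)`, rescaled so its maximum is
#' exactly 1; an event of amplitude `A` then contributes a phasic excursion
#' whose peak equals `A`.
#'
#' @param t times since event onset (s); values `< 0` give 0.
#' @param tau_rise_s,tau_decay_s rise and decay constants (s),
#'   `tau_decay_s > tau_rise_s`.
#' @return kernel values, same length as `t`.
#' @examples
#' max(scr_kernel(seq(0, 30, by = 0.001))) # 1
#' @export
scr_kernel <- function(t, tau_rise_s = 0.75, tau_decay_s = 4) {
  if (tau_decay_s <= tau_rise_s)
    stopf("parameter_error", "tau_decay_s must exceed tau_rise_s")
  # analytic peak of the raw difference, used for unit-peak normalization
  tpk <- tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
  pk <- exp(-tpk / tau_decay_s) - exp(-tpk / tau_rise_s)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay_s) - exp(-t[pos] / tau_rise_s)) / pk
  out
}

# internal: constant-rate segments (s, s, events/s, kPa) covering the span
rate_segments <- function(profile, schedule) {
  ep <- schedule$epochs
  base <- profile$scr_rate_base_per_min / 60
  gain <- profile$scr_rate_gain_per_kPa / 60
  segs <- data.frame(t0 = numeric(0), t1 = numeric(0),
                     rate = numeric(0), pressure = numeric(0))
  cur <- 0
  for (i in seq_len(nrow(ep))) {
    on <- ep$onset_s[i]; off <- on + ep$duration_s[i]
    if (on > cur)
      segs <- rbind(segs, data.frame(t0 = cur, t1 = on, rate = base, pressure = 0))
    segs <- rbind(segs, data.frame(t0 = on, t1 = off,
                                   rate = base + gain * ep$pressure_kPa[i],
                                   pressure = ep$pressure_kPa[i]))
    cur <- off
  }
  if (cur < schedule$span_s)
    segs <- rbind(segs, data.frame(t0 = cur, t1 = schedule$span_s,
                                   rate = base, pressure = 0))
  segs
}

# internal: raised-cosine on/off ramp for the pressure-coupled tonic term
tonic_ramp <- function(t, onset, offset, ramp_s = 2) {
  r <- numeric(length(t))
  up <- t >= onset & t < onset + ramp_s
  r[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp_s))
  r[t >= onset + ramp_s & t < offset] <- 1
  dn <- t >= offset & t < offset + ramp_s
  r[dn] <- 0.5 * (1 + cos(pi * (t[dn] - offset) / ramp_s))
  r
}

#' Simulate a skin-conductance recording
#'
#' The trace is the sum of a tonic term (baseline level, slow linear drift,
#' and a pressure-coupled shift ramped with a 2-s raised cosine at epoch
#' edges), a phasic term (a Poisson train of unit-peak Bateman kernels whose
#' rate and lognormal amplitudes grow linearly with the epoch pressure), and
#' white Gaussian measurement noise. The event train and the noise use
#' separate derived substreams of `seed` (see [substream_seed()]).
#'
#' @param profile a [subject_profile()].
#' @param schedule a [stimulus_schedule()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param scr_events optional data.frame (`time_s`, `amplitude_uS`) of forced
#'   SCR events; when supplied, no random events are drawn.
#' @return an [eda_recording()] with an extra element `scr_events`, the
#'   ground-truth event train (`time_s`, `amplitude_uS`, `pressure_kPa`).
#' @examples
#' prof <- subject_profile(scr_rate_base_per_min = 0, scl_drift_uS_per_s = 0)
#' sch <- protocol_schedule(60, c(10, 20, 30))
#' rec <- simulate_eda(prof, sch, sim_config(fs_eda_hz = 50,
#'                     eda_noise_sd_uS = 0), seed = 1)
#' @export
simulate_eda <- function(profile, schedule, config = sim_config(), seed = 1,
                         scr_events = NULL) {
  if (!inherits(profile, "subject_profile"))
    stopf("parameter_error", "profile must be a subject_profile")
  if (!inherits(schedule, "stimulus_schedule"))
    stopf("parameter_error", "schedule must be a stimulus_schedule")
  fs <- config$fs_eda_hz
  n <- floor(schedule$span_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs

  ep <- schedule$epochs
  tonic <- profile$scl_baseline_uS + profile$scl_drift_uS_per_s * t
  for (i in seq_len(nrow(ep)))
    tonic <- tonic + profile$tonic_gain_uS_per_kPa * ep$pressure_kPa[i] *
      tonic_ramp(t, ep$onset_s[i], ep$onset_s[i] + ep$duration_s[i])

  if (is.null(scr_events)) {
    set.seed(substream_seed(seed, 0L, 1L))
    segs <- rate_segments(profile, schedule)
    evs <- lapply(seq_len(nrow(segs)), function(i) {
      dur <- segs$t1[i] - segs$t0[i]
      nev <- rpois(1, segs$rate[i] * dur)
      if (nev == 0)
        return(data.frame(time_s = numeric(0), amplitude_uS = numeric(0),
                          pressure_kPa = numeric(0)))
      med <- profile$scr_amp_median_uS *
        (1 + profile$scr_amp_gain_per_kPa * segs$pressure[i])
      data.frame(
        time_s = sort(segs$t0[i] + runif(nev) * dur),
        amplitude_uS = rlnorm(nev, meanlog = log(med),
                              sdlog = config$scr_amp_sdlog),
        pressure_kPa = segs$pressure[i]
      )
    })
    events <- do.call(rbind, evs)
  } else {
    if (!all(c("time_s", "amplitude_uS") %in% names(scr_events)))
      stopf("parameter_error", "scr_events needs columns time_s, amplitude_uS")
    events <- data.frame(time_s = scr_events$time_s,
                         amplitude_uS = scr_events$amplitude_uS,
                         pressure_kPa = NA_real_)
  }

  phasic <- numeric(n)
  if (nrow(events)) {
    support <- 12 * config$scr_tau_decay_s
    for (i in seq_len(nrow(events))) {
      te <- events$time_s[i]
      i0 <- max(1L, ceiling(te * fs) + 1L)
      i1 <- min(n, floor((te + support) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      phasic[idx] <- phasic[idx] + events$amplitude_uS[i] *
        scr_kernel(t[idx] - te, config$scr_tau_rise_s, config$scr_tau_decay_s)
    }
  }

  noise <- 0
  if (config$eda_noise_sd_uS > 0) {
    set.seed(substream_seed(seed, 0L, 2L))
    noise <- rnorm(n, 0, config$eda_noise_sd_uS)
  }

  rec <- eda_recording(time_s = t, eda_uS = tonic + phasic + noise, fs_hz = fs)
  rec$scr_events <- events
  rec
}
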