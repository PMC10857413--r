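#' Simulate per-epoch VAS ratings
#'
#' Raw ratings follow `clip(vas_sensitivity * P / 6 + noise, 0, 10)`, so a
#' subject with sensitivity 1 rates the 60 kPa anchor at the top of the
#' scale before noise. The anchor rating is generated by the same stochastic
#' rule (not pinned at 10), so normalization against it is non-trivial.
#'
#' @inheritParams simulate_eda
#' @param noise_sd SD of the Gaussian rating noise on the 0-10 scale.
#' @return an object of class `vas_record`: a list with `ratings` (data.frame
#'   `onset_s`, `pressure_kPa`, `vas_raw` for the pressure epochs) and
#'   `anchor` (list `pressure_kPa`, `vas_raw`).
#' @examples
#' simulate_vas(subject_profile(), protocol_schedule(60), seed = 1)
#' @export
simulate_vas <- function(profile, schedule, seed = 1, noise_sd = 0.5) {
  if (!inherits(profile, "subject_profile"))
    stopf("parameter_error", "profile must be a subject_profile")
  if (!inherits(schedule, "stimulus_schedule"))
    stopf("parameter_error", "schedule must be a stimulus_schedule")
  set.seed(substream_seed(seed, 0L, 4L))
  rate1 <- function(p) {
    raw <- profile$vas_sensitivity * p / 6 + rnorm(1, 0, noise_sd)
    min(max(raw, 0), 10)
  }
  anchor <- list(pressure_kPa = schedule$anchor_pressure_kPa,
                 vas_raw = rate1(schedule$anchor_pressure_kPa))
  pe <- pressure_epochs(schedule)
  ratings <- data.frame(
    onset_s = pe$onset_s,
    pressure_kPa = pe$pressure_kPa,
    vas_raw = vapply(pe$pressure_kPa, rate1, numeric(1))
  )
  structure(list(ratings = ratings, anchor = anchor), class = "vas_record")
}
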