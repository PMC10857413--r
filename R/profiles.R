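#' Construct and validate a subject profile
#'
#' A subject profile holds the per-subject physiological parameters that the
#' simulator couples to cuff pressure: tonic skin conductance level and its
#' slow drift, SCR event rates and amplitudes (with linear pressure gains),
#' the tissue-oxygen-saturation response (baseline, maximal drop at/above the
#' occlusion pressure, exponential time constant), and the VAS sensitivity.
#'
#' @param subject_id character label.
#' @param scl_baseline_uS resting skin conductance level (uS, > 0).
#' @param scl_drift_uS_per_s slow session-scale tonic drift (uS/s; usually
#'   negative, reflecting habituation of the sweat response over the session).
#' @param scr_rate_base_per_min spontaneous SCR rate at 0 kPa (events/min,
#'   >= 0).
#' @param scr_rate_gain_per_kPa SCR rate increase per kPa of cuff pressure
#'   (events/min/kPa, >= 0).
#' @param scr_amp_median_uS median SCR amplitude at 0 kPa (uS, > 0);
#'   amplitudes are lognormal.
#' @param scr_amp_gain_per_kPa multiplicative amplitude gain per kPa (>= 0):
#'   the lognormal median at pressure P is
#'   `scr_amp_median_uS * (1 + scr_amp_gain_per_kPa * P)`.
#' @param tonic_gain_uS_per_kPa pressure-coupled tonic shift (uS/kPa, >= 0).
#' @param sto2_baseline_pct resting tissue oxygen saturation (%, 0-100).
#' @param sto2_drop_max_pct asymptotic StO2 decrease at/above the occlusion
#'   pressure (percentage points; must not exceed the baseline).
#' @param sto2_tau_s exponential time constant of the StO2 response (s, > 0).
#' @param vas_sensitivity scalar mapping pressure to the raw VAS rating
#'   (> 0); raw VAS = `vas_sensitivity * P / 6` before noise and clipping,
#'   so sensitivity 1 saturates the 0-10 scale exactly at the 60 kPa anchor.
#' @return an object of class `subject_profile` (a named list).
#' @seealso [sample_subject()], [default_population()]
#' @export
subject_profile <- function(subject_id = "S01",
                            scl_baseline_uS = 8,
                            scl_drift_uS_per_s = 0,
                            scr_rate_base_per_min = 4,
                            scr_rate_gain_per_kPa = 0.36,
                            scr_amp_median_uS = 0.18,
                            scr_amp_gain_per_kPa = 0.05,
                            tonic_gain_uS_per_kPa = 0.002,
                            sto2_baseline_pct = 70,
                            sto2_drop_max_pct = 57,
                            sto2_tau_s = 45,
                            vas_sensitivity = 1) {
  p <- list(
    subject_id = as.character(subject_id),
    scl_baseline_uS = assert_number(scl_baseline_uS, "scl_baseline_uS", lower = 1e-9),
    scl_drift_uS_per_s = assert_number(scl_drift_uS_per_s, "scl_drift_uS_per_s"),
    scr_rate_base_per_min = assert_number(scr_rate_base_per_min, "scr_rate_base_per_min", lower = 0),
    scr_rate_gain_per_kPa = assert_number(scr_rate_gain_per_kPa, "scr_rate_gain_per_kPa", lower = 0),
    scr_amp_median_uS = assert_number(scr_amp_median_uS, "scr_amp_median_uS", lower = 1e-12),
    scr_amp_gain_per_kPa = assert_number(scr_amp_gain_per_kPa, "scr_amp_gain_per_kPa", lower = 0),
    tonic_gain_uS_per_kPa = assert_number(tonic_gain_uS_per_kPa, "tonic_gain_uS_per_kPa", lower = 0),
    sto2_baseline_pct = assert_number(sto2_baseline_pct, "sto2_baseline_pct", lower = 0, upper = 100),
    sto2_drop_max_pct = assert_number(sto2_drop_max_pct, "sto2_drop_max_pct", lower = 0, upper = 100),
    sto2_tau_s = assert_number(sto2_tau_s, "sto2_tau_s", lower = 1e-9),
    vas_sensitivity = assert_number(vas_sensitivity, "vas_sensitivity", lower = 1e-12)
  )
  if (p$sto2_baseline_pct - p$sto2_drop_max_pct < 0)
    stopf("parameter_error",
          "sto2_drop_max_pct (%g) exceeds sto2_baseline_pct (%g)",
          p$sto2_drop_max_pct, p$sto2_baseline_pct)
  structure(p, class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile>", x$subject_id, "\n")
  flds <- setdiff(names(x), "subject_id")
  for (f in flds) cat(sprintf("  %-24s %g\n", f, x[[f]]))
  invisible(x)
}

#' Default population parameters for the synthetic cohort generator
#'
#' One row per [subject_profile()] field, giving the population mean, the
#' dispersion and the sampling family used by [sample_subject()]:
#' `"lognormal"` (dispersion = coefficient of variation; mean-preserving
#' parameterisation) for positive scale parameters, `"normal"` (dispersion =
#' SD) for parameters that may take either sign.
#'
#' The default means were calibrated once, by seed-swept simulation of both
#' experimental designs, so that cohort-level feature means land on the scale
#' of published thigh-cuff experiments (SCR counts of roughly 5-12 per minute
#' rising with pressure over 10-30 kPa, maximum SCR amplitudes of 1-2 uS,
#' StO2 decreases of roughly 11/56/58 percentage points at 10/20/30 kPa with
#' a vascular-occlusion plateau above 20 kPa). The methods vignette describes
#' the calibration and its limits.
#'
#' @return a data.frame with columns `field`, `mean`, `dispersion`, `dist`.
#' @export
default_population <- function() {
  d <- rbind(
    data.frame(field = "scl_baseline_uS",       mean = 8.0,     dispersion = 0.25, dist = "lognormal"),
    data.frame(field = "scl_drift_uS_per_s",    mean = -0.0033, dispersion = 0.0015, dist = "normal"),
    data.frame(field = "scr_rate_base_per_min", mean = 4.0,     dispersion = 0.30, dist = "lognormal"),
    data.frame(field = "scr_rate_gain_per_kPa", mean = 0.36,    dispersion = 0.30, dist = "lognormal"),
    data.frame(field = "scr_amp_median_uS",     mean = 0.18,    dispersion = 0.30, dist = "lognormal"),
    data.frame(field = "scr_amp_gain_per_kPa",  mean = 0.05,    dispersion = 0.30, dist = "lognormal"),
    data.frame(field = "tonic_gain_uS_per_kPa", mean = 0.002,   dispersion = 0.30, dist = "lognormal"),
    data.frame(field = "sto2_baseline_pct",     mean = 70,      dispersion = 4,    dist = "normal"),
    data.frame(field = "sto2_drop_max_pct",     mean = 57,      dispersion = 0.15, dist = "lognormal"),
    data.frame(field = "sto2_tau_s",            mean = 45,      dispersion = 0.20, dist = "lognormal"),
    data.frame(field = "vas_sensitivity",       mean = 1.0,     dispersion = 0.25, dist = "lognormal")
  )
  rownames(d) <- NULL
  d
}

#' Draw one subject profile from a population parameter table
#'
#' Positive scale parameters are drawn from mean-preserving lognormals
#' (`meanlog = log(mean / sqrt(1 + cv^2))`, `sdlog = sqrt(log(1 + cv^2))`),
#' signed parameters from normals. Zero dispersion returns the population
#' mean exactly. The StO2 drop is truncated so it never exceeds the drawn
#' baseline (profile invariant).
#'
#' @param population a data.frame as returned by [default_population()];
#'   columns `field`, `mean`, `dispersion`, `dist`.
#' @param seed integer seed; identical seeds give identical profiles.
#' @param subject_id label for the drawn subject.
#' @return a [subject_profile()].
#' @examples
#' sample_subject(default_population(), seed = 1)
#' @export
sample_subject <- function(population, seed, subject_id = "S01") {
  if (!is.data.frame(population) ||
      !all(c("field", "mean", "dispersion", "dist") %in% names(population)))
    stopf("parameter_error",
          "population must have columns field, mean, dispersion, dist")
  if (any(population$dispersion < 0))
    stopf("parameter_error", "negative dispersion in population table")
  if (any(!population$dist %in% c("lognormal", "normal")))
    stopf("parameter_error", "dist must be 'lognormal' or 'normal'")
  set.seed(substream_seed(seed, 0L, 0L))
  vals <- mapply(function(mean, disp, dist) {
    if (disp == 0) return(mean)
    if (dist == "lognormal") {
      if (mean <= 0)
        stopf("parameter_error", "lognormal fields need a positive mean")
      sdlog <- sqrt(log(1 + disp^2))
      rlnorm(1, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    } else {
      rnorm(1, mean, disp)
    }
  }, population$mean, population$dispersion, population$dist)
  args <- as.list(setNames(vals, population$field))
  # enforce the joint invariant baseline - drop >= 0 by truncation
  if (!is.null(args$sto2_baseline_pct)) {
    args$sto2_baseline_pct <- min(max(args$sto2_baseline_pct, 0), 100)
    if (!is.null(args$sto2_drop_max_pct))
      args$sto2_drop_max_pct <- min(args$sto2_drop_max_pct, args$sto2_baseline_pct)
  }
  do.call(subject_profile, c(list(subject_id = subject_id), args))
}
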