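#' Simulate a full experimental cohort
#'
#' Draws one [subject_profile()] per subject from the design's population
#' table, builds each subject's [protocol_schedule()] (condition order
#' permuted independently per subject when `randomize_order`), and simulates
#' the EDA trace, the NIRS trace (designs with `with_nirs`) and the VAS
#' ratings. Everything derives from the single master `seed` through the
#' documented substream scheme ([substream_seed()]), so a cohort is a pure
#' function of `(design, seed)`.
#'
#' @param design a [cohort_design()].
#' @param seed master seed.
#' @param dir optional directory; when given, the cohort is also written to
#'   disk via [write_cohort()] (one subdirectory per subject plus a
#'   `manifest.json`).
#' @return an object of class `cuff_cohort`: `design`, `seed`, and
#'   `subjects`, a list of per-subject lists with elements `profile`,
#'   `schedule`, `eda`, `nirs` (or `NULL`), `vas`.
#' @examples
#' design <- cohort_design(n_subjects = 2, epoch_duration_s = 60,
#'                         sim_config = sim_config(fs_eda_hz = 20))
#' coh <- simulate_cohort(design, seed = 1)
#' @export
simulate_cohort <- function(design, seed = 1, dir = NULL) {
  if (!inherits(design, "cohort_design"))
    stopf("parameter_error", "design must be a cohort_design")
  subjects <- vector("list", design$n_subjects)
  for (i in seq_len(design$n_subjects)) {
    s_i <- substream_seed(seed, i, 9L)
    sid <- sprintf("S%02d", i)
    profile <- sample_subject(design$population, s_i, subject_id = sid)
    order_k <- design$pressures_kPa
    if (design$randomize_order) {
      set.seed(substream_seed(s_i, 0L, 5L))
      order_k <- sample(order_k)
    }
    schedule <- protocol_schedule(
      epoch_duration_s = design$epoch_duration_s,
      pressures_kPa = order_k,
      rest_s = design$rest_s,
      lead_in_s = design$lead_in_s
    )
    eda <- simulate_eda(profile, schedule, design$sim_config, seed = s_i)
    nirs <- if (design$with_nirs)
      simulate_nirs(profile, schedule, design$sim_config, seed = s_i)
    vas <- simulate_vas(profile, schedule, seed = s_i,
                        noise_sd = design$sim_config$vas_noise_sd)
    subjects[[i]] <- list(profile = profile, schedule = schedule,
                          eda = eda, nirs = nirs, vas = vas, seed = s_i)
  }
  cohort <- structure(list(design = design, seed = seed, subjects = subjects),
                      class = "cuff_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.cuff_cohort <- function(x, ...) {
  cat(sprintf(
    "<cuff_cohort> %d subjects, %g-s epochs at %s kPa, %s, seed %s\n",
    length(x$subjects), x$design$epoch_duration_s,
    paste(x$design$pressures_kPa, collapse = "/"),
    if (x$design$with_nirs) "EDA+NIRS" else "EDA only", format(x$seed)))
  invisible(x)
}

#' Simulate a null feature table
#'
#' A balanced within-subject table with *no* condition effect: each
#' observation is a subject-level random intercept plus independent noise.
#' Used to check the type-I error calibration of the repeated-measures
#' ANOVA stage.
#'
#' @param n_subjects number of subjects.
#' @param pressures_kPa condition labels.
#' @param seed integer seed.
#' @param between_sd SD of the subject random intercepts.
#' @param within_sd SD of the observation noise.
#' @return a data.frame with columns `subject`, `pressure_kPa`, `value`.
#' @export
simulate_null_feature_table <- function(n_subjects = 13,
                                        pressures_kPa = c(10, 20, 30),
                                        seed = 1, between_sd = 1,
                                        within_sd = 1) {
  set.seed(substream_seed(seed, 0L, 6L))
  k <- length(pressures_kPa)
  subj <- sprintf("S%02d", seq_len(n_subjects))
  intercepts <- rnorm(n_subjects, 0, between_sd)
  data.frame(
    subject = rep(subj, each = k),
    pressure_kPa = rep(pressures_kPa, n_subjects),
    value = rep(intercepts, each = k) + rnorm(n_subjects * k, 0, within_sd)
  )
}
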