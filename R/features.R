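#' Feature-extraction parameters
#'
#' Collects the tunable settings of the feature stage in one validated
#' list: the high-pass cutoff of the tonic/phasic decomposition, the SCR
#' detector settings, the EDA baseline window, and the StO2 block-averaging
#' windows.
#'
#' @param fc_hz tonic/phasic high-pass cutoff (Hz).
#' @param threshold_uS SCR detection threshold (uS).
#' @param min_separation_s SCR merge distance (s).
#' @param smooth_s phasic smoothing before the extremum scan (s).
#' @param eda_baseline_s length of the pre-epoch EDA baseline window (s).
#' @param decimate_to_hz optional EDA decimation target before filtering
#'   (Hz); `NULL` keeps the recorded rate.
#' @param block_s StO2 averaging block (s).
#' @param nirs_baseline_s pre-epoch StO2 baseline window (s).
#' @param block_stat `"last"` or `"min"` block rule for the StO2 decrease.
#' @return a list of class `feature_params`.
#' @export
feature_params <- function(fc_hz = 0.05, threshold_uS = 0.01,
                           min_separation_s = 1, smooth_s = 0.2,
                           eda_baseline_s = 10, decimate_to_hz = NULL,
                           block_s = 30, nirs_baseline_s = 30,
                           block_stat = c("last", "min")) {
  structure(list(
    fc_hz = assert_number(fc_hz, "fc_hz", lower = 1e-12),
    threshold_uS = assert_number(threshold_uS, "threshold_uS", lower = 0),
    min_separation_s = assert_number(min_separation_s, "min_separation_s", lower = 0),
    smooth_s = assert_number(smooth_s, "smooth_s", lower = 0),
    eda_baseline_s = assert_number(eda_baseline_s, "eda_baseline_s", lower = 1e-9),
    decimate_to_hz = if (is.null(decimate_to_hz)) NULL else
      assert_number(decimate_to_hz, "decimate_to_hz", lower = 1e-9),
    block_s = assert_number(block_s, "block_s", lower = 1e-9),
    nirs_baseline_s = assert_number(nirs_baseline_s, "nirs_baseline_s", lower = 1e-9),
    block_stat = match.arg(block_stat)
  ), class = "feature_params")
}

# internal: features for one simulated subject, one row per pressure epoch
subject_features <- function(subject, params) {
  dec <- decompose_eda(subject$eda, fc_hz = params$fc_hz,
                       decimate_to_hz = params$decimate_to_hz)
  sto2 <- if (!is.null(subject$nirs)) compute_sto2(subject$nirs)
  pe <- pressure_epochs(subject$schedule)
  anchor_raw <- subject$vas$anchor$vas_raw
  rows <- lapply(seq_len(nrow(pe)), function(i) {
    epoch <- c(pe$onset_s[i], pe$onset_s[i] + pe$duration_s[i])
    baseline <- c(epoch[1] - params$eda_baseline_s, epoch[1])
    f <- extract_eda_features(dec, epoch, baseline,
                              threshold_uS = params$threshold_uS,
                              min_separation_s = params$min_separation_s,
                              smooth_s = params$smooth_s)
    drop <- if (!is.null(sto2))
      compute_sto2_decrease(sto2, epoch, block_s = params$block_s,
                            baseline_s = params$nirs_baseline_s,
                            block_stat = params$block_stat)$decrease_pct
    else NA_real_
    vr <- subject$vas$ratings
    raw <- vr$vas_raw[match(pe$onset_s[i], vr$onset_s)]
    data.frame(
      subject = subject$profile$subject_id,
      pressure_kPa = pe$pressure_kPa[i],
      mean_scl_uS = f$mean_scl_uS,
      max_scr_amp_uS = f$max_scr_amp_uS,
      scr_count = f$scr_count,
      sto2_decrease_pct = drop,
      vas_raw = raw,
      vas_norm_pct = suppressWarnings(normalize_vas(raw, anchor_raw))
    )
  })
  do.call(rbind, rows)
}

#' Build the cohort feature table
#'
#' One row per subject x pressure condition with all extracted features:
#' the three EDA markers, the StO2 decrease (designs with NIRS; `NA`
#' otherwise), and the raw and anchor-normalized VAS. Rows are sorted by
#' subject and pressure, giving the complete balanced within-subject layout
#' the inference stage requires.
#'
#' @param cohort a [simulate_cohort()] result or a cohort loaded with
#'   [read_cohort()].
#' @param params a [feature_params()].
#' @return a data.frame (columns `subject`, `pressure_kPa`, `mean_scl_uS`,
#'   `max_scr_amp_uS`, `scr_count`, `sto2_decrease_pct`, `vas_raw`,
#'   `vas_norm_pct`).
#' @export
build_feature_table <- function(cohort, params = feature_params()) {
  if (!inherits(cohort, "cuff_cohort"))
    stopf("parameter_error", "cohort must be a cuff_cohort")
  if (!inherits(params, "feature_params"))
    stopf("parameter_error", "params must be a feature_params")
  tab <- do.call(rbind, lapply(cohort$subjects, subject_features,
                               params = params))
  tab <- tab[order(tab$subject, tab$pressure_kPa), ]
  if (all(is.na(tab$sto2_decrease_pct))) tab$sto2_decrease_pct <- NULL
  rownames(tab) <- NULL
  tab
}

# internal: long table -> wide n x k matrix for one feature, validated
feature_wide <- function(table, feature) {
  for (col in c("subject", "pressure_kPa"))
    if (is.null(table[[col]]))
      stopf("design_error", "feature table lacks column '%s'", col)
  if (is.null(table[[feature]]))
    stopf("design_error", "feature '%s' not in table", feature)
  if (any(is.na(table[[feature]])))
    stopf("design_error", "feature '%s' contains missing values", feature)
  subs <- unique(table$subject)
  conds <- sort(unique(table$pressure_kPa))
  if (nrow(table) != length(subs) * length(conds))
    stopf("design_error",
          "incomplete design: %d rows for %d subjects x %d conditions",
          nrow(table), length(subs), length(conds))
  wide <- matrix(NA_real_, length(subs), length(conds),
                 dimnames = list(subs, as.character(conds)))
  for (r in seq_len(nrow(table))) {
    i <- match(table$subject[r], subs)
    j <- match(table$pressure_kPa[r], conds)
    if (!is.na(wide[i, j]))
      stopf("design_error", "duplicate cell: subject %s at %g kPa",
            table$subject[r], table$pressure_kPa[r])
    wide[i, j] <- table[[feature]][r]
  }
  if (any(is.na(wide)))
    stopf("design_error", "incomplete design: some subject x condition cells missing")
  wide
}
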