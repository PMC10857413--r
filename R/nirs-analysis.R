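#' Construct a NIRS recording
#'
#' Paired oxygenated/deoxygenated hemoglobin traces in arbitrary
#' concentration units, uniformly sampled (default 5 Hz).
#'
#' @param time_s sample times (s).
#' @param oxyHb_au,deoxyHb_au hemoglobin signals (arbitrary units), finite.
#' @param fs_hz sampling rate (Hz); defaults to the inverse median step.
#' @return an object of class `nirs_recording`.
#' @export
nirs_recording <- function(time_s, oxyHb_au, deoxyHb_au, fs_hz = NULL) {
  if (length(time_s) != length(oxyHb_au) ||
      length(time_s) != length(deoxyHb_au))
    stopf("data_error", "time_s, oxyHb_au, deoxyHb_au lengths differ")
  if (length(time_s) < 2)
    stopf("data_error", "recording needs at least 2 samples")
  if (any(!is.finite(oxyHb_au)) || any(!is.finite(deoxyHb_au)))
    stopf("data_error", "non-finite hemoglobin samples")
  dt <- diff(time_s)
  if (is.null(fs_hz)) fs_hz <- 1 / median(dt)
  assert_number(fs_hz, "fs_hz", lower = 1e-12)
  if (any(abs(dt - 1 / fs_hz) > 1e-6 * (1 / fs_hz)))
    stopf("sampling_error", "non-uniform sampling in NIRS recording")
  structure(list(time_s = as.numeric(time_s), oxyHb_au = as.numeric(oxyHb_au),
                 deoxyHb_au = as.numeric(deoxyHb_au), fs_hz = fs_hz),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %d samples @ %g Hz, %.1f s\n",
              length(x$time_s), x$fs_hz, diff(range(x$time_s))))
  invisible(x)
}

#' Compute tissue oxygen saturation from oxy/deoxy-hemoglobin
#'
#' `StO2 = 100 * oxyHb / (oxyHb + deoxyHb)` per sample. Samples whose total
#' hemoglobin is non-positive, or whose ratio falls outside 0-100 %, are
#' flagged invalid rather than raising an error; downstream block averages
#' skip them. StO2 is invariant to any common positive rescaling of the two
#' channels.
#'
#' @param recording a [nirs_recording()].
#' @return an object of class `sto2_series`: `time_s`, `sto2_pct`,
#'   `valid_mask`, `fs_hz`.
#' @examples
#' rec <- nirs_recording(0:9, rep(3, 10), rep(1, 10))
#' compute_sto2(rec)$sto2_pct[1] # 75
#' @export
compute_sto2 <- function(recording) {
  if (!inherits(recording, "nirs_recording"))
    stopf("parameter_error", "recording must be a nirs_recording")
  total <- recording$oxyHb_au + recording$deoxyHb_au
  sto2 <- rep(NA_real_, length(total))
  ok <- total > 0
  sto2[ok] <- 100 * recording$oxyHb_au[ok] / total[ok]
  valid <- ok & !is.na(sto2) & sto2 >= 0 & sto2 <= 100
  structure(list(time_s = recording$time_s, sto2_pct = sto2,
                 valid_mask = valid, fs_hz = recording$fs_hz),
            class = "sto2_series")
}

#' Per-epoch decrease in StO2 with 30-s block averaging
#'
#' The saturation is averaged over consecutive 30-s blocks from the moment
#' of pressure application; the decrease is the pre-epoch baseline block
#' mean minus the mean of the final full block (or of the minimum block,
#' with `block_stat = "min"`), in percentage points. Partial trailing
#' blocks are discarded. Invalid samples are excluded from all means.
#'
#' @param series an [compute_sto2()] result.
#' @param epoch numeric `(start_s, end_s)`, half-open.
#' @param block_s averaging block length (s).
#' @param baseline_s length of the pre-onset baseline window (s).
#' @param block_stat which block defines the decrease: the last full block
#'   (default) or the minimum block mean.
#' @return an object of class `sto2_decrease`: `baseline_pct`,
#'   `block_means_pct`, `decrease_pct`.
#' @export
compute_sto2_decrease <- function(series, epoch, block_s = 30,
                                  baseline_s = 30,
                                  block_stat = c("last", "min")) {
  if (!inherits(series, "sto2_series"))
    stopf("parameter_error", "series must be an sto2_series")
  block_stat <- match.arg(block_stat)
  assert_number(block_s, "block_s", lower = 1e-9)
  assert_number(baseline_s, "baseline_s", lower = 1e-9)
  dur <- epoch[2] - epoch[1]
  nblock <- floor(dur / block_s + 1e-9)
  if (nblock < 1)
    stopf("duration_error",
          "epoch (%.1f s) shorter than one %g-s block", dur, block_s)
  t <- series$time_s
  block_mean <- function(t0, t1, what) {
    idx <- interval_index(t, c(t0, t1), what)
    idx <- idx[series$valid_mask[idx]]
    if (!length(idx))
      stopf("data_error", "all samples invalid in %s [%g, %g)", what, t0, t1)
    mean(series$sto2_pct[idx])
  }
  baseline <- block_mean(epoch[1] - baseline_s, epoch[1], "baseline")
  blocks <- vapply(seq_len(nblock) - 1L, function(k)
    block_mean(epoch[1] + k * block_s, epoch[1] + (k + 1) * block_s,
               sprintf("block %d", k + 1L)), numeric(1))
  ref <- if (block_stat == "last") blocks[nblock] else min(blocks)
  structure(list(baseline_pct = baseline, block_means_pct = blocks,
                 decrease_pct = baseline - ref, block_stat = block_stat),
            class = "sto2_decrease")
}
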