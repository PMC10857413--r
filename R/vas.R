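#' Normalize a VAS rating against the 60 kPa anchor
#'
#' Discomfort ratings differ in scale between subjects (threshold bias), so
#' each raw 0-10 rating is expressed as a percentage of the subject's own
#' rating of a fixed 60 kPa anchor application:
#' `normalized VAS = 100 * vas_raw / anchor_raw` (percent).
#'
#' Values above 100 % are allowed (a condition rated above the anchor) and
#' produce a warning; a non-positive anchor is an error, not a silent NaN,
#' since the normalization baseline is then undefined.
#'
#' @param vas_raw raw rating(s) in `[0, 10]`.
#' @param anchor_raw the subject's anchor rating, in `(0, 10]`.
#' @return normalized rating(s) in percent.
#' @examples
#' normalize_vas(4, 8)  # 50
#' normalize_vas(6, 6)  # 100
#' @export
normalize_vas <- function(vas_raw, anchor_raw) {
  if (!is.numeric(vas_raw) || any(!is.finite(vas_raw)) ||
      any(vas_raw < 0) || any(vas_raw > 10))
    stopf("parameter_error", "vas_raw must be within [0, 10]")
  if (!is.numeric(anchor_raw) || length(anchor_raw) != 1L ||
      !is.finite(anchor_raw))
    stopf("normalization_error", "anchor_raw must be a single finite rating")
  if (anchor_raw <= 0)
    stopf("normalization_error",
          "anchor rating must be positive (got %g): normalization undefined",
          anchor_raw)
  out <- 100 * vas_raw / anchor_raw
  if (any(out > 100))
    warning("normalized VAS exceeds 100% (rating above the 60 kPa anchor)",
            call. = FALSE)
  out
}
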