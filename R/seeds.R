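#' Derive a reproducible substream seed
#'
#' The simulator uses one master seed per cohort and derives independent
#' substreams for every (subject, signal) pair with a fixed counter scheme,
#' so adding a subject or skipping a signal never perturbs the others.
#' The scheme is a Lehmer-style multiplicative hash reduced modulo
#' `2^31 - 1`; all intermediate products stay below 2^53 so the arithmetic
#' is exact in double precision.
#'
#' Stream codes used by the package: 0 profile sampling, 1 SCR event train,
#' 2 EDA measurement noise, 3 NIRS, 4 VAS, 5 condition-order permutation.
#'
#' @param seed master seed (non-negative integer, < 2^31).
#' @param subject subject counter (0 for cohort-level streams).
#' @param stream stream code (small non-negative integer).
#' @return an integer seed in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' substream_seed(42, subject = 3, stream = 1)
#' @export
substream_seed <- function(seed, subject = 0L, stream = 0L) {
  assert_number(seed, "seed", lower = 0)
  assert_number(subject, "subject", lower = 0)
  assert_number(stream, "stream", lower = 0)
  m <- 2147483647 # 2^31 - 1
  h <- ((seed %% m) * 48271) %% m
  h <- ((h + subject * 40503 + stream * 997 + 1) * 16807) %% m
  as.integer(h)
}
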