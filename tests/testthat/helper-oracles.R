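# Independent first-principles oracles. These deliberately avoid the code
# paths (and the packages) used by the implementation: sums of squares by
# explicit double loops, correlation by direct summation, peak scanning by a
# sample-by-sample walk.

# Repeated-measures ANOVA from raw sums of squares (wide = n x k matrix)
oracle_rm_anova <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  cond_means <- numeric(k); subj_means <- numeric(n)
  for (j in 1:k) cond_means[j] <- mean(wide[, j])
  for (i in 1:n) subj_means[i] <- mean(wide[i, ])
  ss_cond <- 0; ss_int <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (cond_means[j] - grand)^2
  for (i in 1:n) for (j in 1:k)
    ss_int <- ss_int + (wide[i, j] - cond_means[j] - subj_means[i] + grand)^2
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_int / df2)
  list(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Greenhouse-Geisser epsilon from the full k x k covariance (classic form)
oracle_gg_epsilon <- function(wide) {
  k <- ncol(wide)
  S <- matrix(0, k, k)
  cm <- colMeans(wide)
  for (i in seq_len(nrow(wide)))
    S <- S + tcrossprod(wide[i, ] - cm)
  S <- S / (nrow(wide) - 1)
  sbar <- mean(diag(S)); mbar <- mean(S)
  rowm <- rowMeans(S)
  num <- (k * (sbar - mbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mbar^2)
  num / den
}

oracle_paired_t <- function(x, y) {
  d <- y - x; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in 1:n) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# |H(f)| of the zero-phase (forward-backward) order-2 Butterworth high-pass:
# a single pass has |H1| = w^2 / sqrt(1 + w^4), w = f/fc; two passes square it.
oracle_filtfilt_hp_mag <- function(f, fc) {
  w <- f / fc
  (w^2 / sqrt(1 + w^4))^2
}

# least-squares amplitude of a sinusoid of known frequency in x(t)
fit_sine_amplitude <- function(t, x, freq) {
  X <- cbind(1, sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  b <- qr.solve(X, x)
  sqrt(b[2]^2 + b[3]^2)
}

# Exhaustive extremum-scan SCR detector: walk the samples, track the last
# trough, emit every rise >= threshold, then merge close peaks (keep larger).
oracle_scan_events <- function(t, x, epoch, threshold, min_sep) {
  peaks <- c(); troughs <- c()
  last_min <- 1
  i <- 2
  n <- length(x)
  while (i < n) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      if (x[i] - x[last_min] >= threshold &&
          t[i] >= epoch[1] && t[i] < epoch[2]) {
        peaks <- c(peaks, i); troughs <- c(troughs, last_min)
      }
    }
    if (x[i] < x[i - 1] && x[i] <= x[i + 1]) last_min <- i
    i <- i + 1
  }
  if (!length(peaks))
    return(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      amplitude_uS = numeric(0)))
  ev <- data.frame(onset_s = t[troughs], peak_s = t[peaks],
                   amplitude_uS = x[peaks] - x[troughs])
  repeat {
    gaps <- diff(ev$peak_s)
    j <- which(gaps < min_sep)
    if (!length(j)) break
    j <- j[1]
    drop <- if (ev$amplitude_uS[j] >= ev$amplitude_uS[j + 1]) j + 1 else j
    ev <- ev[-drop, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

# mean of clip(N(mu, sd), lo, hi) in closed form
oracle_clipped_normal_mean <- function(mu, sd, lo = 0, hi = 10) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) - sd * (dnorm(b) - dnorm(a))
}
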