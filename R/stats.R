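#' One-way repeated-measures ANOVA for a feature
#'
#' The standard two-way within-subject decomposition: the condition effect
#' is tested against the condition x subject interaction,
#' `F = MS_condition / MS_interaction` on `(k-1, (k-1)(n-1))` degrees of
#' freedom. The F test is delegated to the multivariate linear model route
#' in base R (`anova.mlm` with spherical contrasts), which also supplies the
#' Greenhouse-Geisser corrected p-value; the Greenhouse-Geisser epsilon is
#' computed from the orthonormal-contrast covariance
#' (`eps = tr(S)^2 / ((k-1) tr(S^2))`).
#'
#' Sphericity was assumed in the source protocol, so `p_value` (uncorrected)
#' is the headline value and `p_value_gg` is reported alongside.
#'
#' @param table long feature table (columns `subject`, `pressure_kPa`, and
#'   the feature), complete and balanced.
#' @param feature name of the feature column to test.
#' @return an object of class `rm_anova_result`: `feature`, `f_value`,
#'   `df_num`, `df_den`, `p_value`, `gg_epsilon`, `p_value_gg`, `n`, `k`.
#' @examples
#' tab <- simulate_null_feature_table(13, seed = 2)
#' rm_anova(tab, "value")
#' @export
rm_anova <- function(table, feature) {
  wide <- feature_wide(table, feature)
  n <- nrow(wide); k <- ncol(wide)
  if (n < 2 || k < 2)
    stopf("design_error", "need at least 2 subjects and 2 conditions")
  scale2 <- sum((wide - mean(wide))^2)
  cmeans <- colMeans(wide)
  ss_cond <- n * sum((cmeans - mean(wide))^2)
  within <- wide - rowMeans(wide)
  ss_int <- sum(sweep(within, 2, colMeans(within))^2)
  tol <- 1e-12 * max(scale2, 1)
  if (ss_int <= tol) {
    if (ss_cond <= tol) {
      # no within-subject variation at all: no condition effect
      return(structure(list(feature = feature, f_value = 0,
                            df_num = k - 1L, df_den = (k - 1L) * (n - 1L),
                            p_value = 1, gg_epsilon = NA_real_,
                            p_value_gg = 1, n = n, k = k),
                       class = "rm_anova_result"))
    }
    stopf("degenerate_data_error",
          "zero interaction mean square: F undefined for '%s'", feature)
  }
  idata <- data.frame(cond = factor(colnames(wide), levels = colnames(wide)))
  ml <- lm(wide ~ 1)
  # suppressWarnings: anova.mlm also computes the Huynh-Feldt correction,
  # whose epsilon can exceed admissible bounds for very small n (NaN p);
  # only the uncorrected and Greenhouse-Geisser columns are used here
  at <- suppressWarnings(anova(ml, M = ~cond, X = ~1, idata = idata,
                               test = "Spherical"))
  structure(list(
    feature = feature,
    f_value = at$F[1],
    df_num = at[["num Df"]][1],
    df_den = at[["den Df"]][1],
    p_value = at[["Pr(>F)"]][1],
    gg_epsilon = gg_epsilon(wide),
    p_value_gg = at[["G-G Pr"]][1],
    n = n, k = k
  ), class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf(
    "RM ANOVA [%s]: F(%d, %d) = %.3f, p = %s (GG eps = %.3f, p_GG = %s)\n",
    x$feature, x$df_num, x$df_den, x$f_value, format_p(x$p_value),
    if (is.na(x$gg_epsilon)) NA else x$gg_epsilon, format_p(x$p_value_gg)))
  invisible(x)
}

# internal: Greenhouse-Geisser epsilon from the wide response matrix
gg_epsilon <- function(wide) {
  k <- ncol(wide)
  S <- var(wide %*% contr.helmert.norm(k))
  sum(diag(S))^2 / ((k - 1) * sum(S * S))
}

# internal: orthonormal contrast matrix (k x k-1)
contr.helmert.norm <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Post hoc paired t-tests between pressure conditions
#'
#' Two-sided paired t-tests on all (or selected) condition pairs, with an
#' optional multiplicity correction. Published post hoc tables of this kind
#' are typically uncorrected, so `correction = "none"` is the default;
#' Holm or Bonferroni are available.
#'
#' @inheritParams rm_anova
#' @param pairs list of 2-vectors of pressures; default all pairs in
#'   increasing order.
#' @param correction `"none"`, `"holm"` or `"bonferroni"`.
#' @param alpha significance level for the `significant` flag (applied to
#'   the corrected p-values).
#' @return a data.frame of class `paired_ttest_result`: one row per pair
#'   with `feature`, `pressure_a`, `pressure_b`, `t_value`, `df`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
paired_ttests <- function(table, feature, pairs = NULL,
                          correction = c("none", "holm", "bonferroni"),
                          alpha = 0.05) {
  correction <- match.arg(correction)
  wide <- feature_wide(table, feature)
  conds <- as.numeric(colnames(wide))
  if (is.null(pairs)) {
    idx <- utils::combn(seq_along(conds), 2, simplify = FALSE)
    pairs <- lapply(idx, function(ij) conds[ij])
  }
  rows <- lapply(pairs, function(pr) {
    ja <- match(as.character(pr[1]), colnames(wide))
    jb <- match(as.character(pr[2]), colnames(wide))
    if (is.na(ja) || is.na(jb))
      stopf("design_error", "pair %g vs %g not in table", pr[1], pr[2])
    d <- wide[, jb] - wide[, ja]
    if (sd(d) == 0) {
      if (all(d == 0)) # identical vectors: no effect, not a pathology
        return(data.frame(feature = feature, pressure_a = pr[1],
                          pressure_b = pr[2], t_value = 0,
                          df = length(d) - 1L, p_value = 1))
      stopf("degenerate_data_error",
            "zero-variance differences for %g vs %g kPa", pr[1], pr[2])
    }
    tt <- t.test(wide[, jb], wide[, ja], paired = TRUE)
    data.frame(feature = feature, pressure_a = pr[1], pressure_b = pr[2],
               t_value = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = correction)
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("paired_ttest_result", "data.frame")
  out
}

#' Pearson correlation between a feature and normalized VAS
#'
#' The product-moment correlation over the pooled subject x condition
#' observations (one r per feature, as published summaries report), with
#' the p-value from the t transform at `n - 2` degrees of freedom.
#' `vas_column = "vas_raw"` switches to raw ratings.
#'
#' @inheritParams rm_anova
#' @param vas_column name of the VAS column to correlate against.
#' @return an object of class `correlation_result`: `feature`, `r`, `n`,
#'   `p_value`.
#' @export
pearson_vs_vas <- function(table, feature, vas_column = "vas_norm_pct") {
  if (is.null(table[[feature]]) || is.null(table[[vas_column]]))
    stopf("design_error", "columns '%s' and '%s' required", feature, vas_column)
  x <- table[[feature]]; y <- table[[vas_column]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stopf("design_error", "need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("degenerate_data_error",
          "zero variance in '%s' or '%s'", feature, vas_column)
  ct <- cor.test(x, y, method = "pearson")
  structure(list(feature = feature, r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson [%s vs VAS]: r = %.3f (n = %d, p = %s)\n",
              x$feature, x$r, x$n, format_p(x$p_value)))
  invisible(x)
}

#' Check RM-ANOVA assumptions for a feature
#'
#' Shapiro-Wilk normality per condition and Mauchly's sphericity test on
#' the within-subject covariance. With two conditions there is a single
#' difference variance, so sphericity holds trivially (`W = 1`).
#'
#' @inheritParams rm_anova
#' @param alpha level used for the `sphericity_ok` flag.
#' @return an object of class `assumption_report`: `feature`, `normality`
#'   (data.frame `pressure_kPa`, `W`, `p_value`), `mauchly_W`, `mauchly_p`,
#'   `sphericity_ok`.
#' @export
check_assumptions <- function(table, feature, alpha = 0.05) {
  wide <- feature_wide(table, feature)
  n <- nrow(wide); k <- ncol(wide)
  if (n < 3)
    stopf("insufficient_data_error", "need at least 3 subjects")
  normality <- do.call(rbind, lapply(seq_len(k), function(j) {
    sw <- shapiro.test(wide[, j])
    data.frame(pressure_kPa = as.numeric(colnames(wide)[j]),
               W = unname(sw$statistic), p_value = sw$p.value)
  }))
  if (k <= 2) {
    mw <- 1; mp <- NA_real_; ok <- TRUE
  } else {
    idata <- data.frame(cond = factor(colnames(wide), levels = colnames(wide)))
    mt <- mauchly.test(lm(wide ~ 1), M = ~cond, X = ~1, idata = idata)
    mw <- unname(mt$statistic); mp <- mt$p.value
    ok <- is.finite(mp) && mp >= alpha
  }
  structure(list(feature = feature, normality = normality,
                 mauchly_W = mw, mauchly_p = mp, sphericity_ok = ok),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("Assumptions [%s]: Mauchly W = %.3f (p = %s), sphericity %s\n",
              x$feature, x$mauchly_W,
              if (is.na(x$mauchly_p)) "NA" else format_p(x$mauchly_p),
              if (x$sphericity_ok) "ok" else "violated"))
  print(x$normality, row.names = FALSE)
  invisible(x)
}
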