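#' Format a mean +/- SD cell
#'
#' Descriptive cells in the summary tables use the `"mean ± SD"` convention
#' with two decimals (one decimal for counts via `digits = 1`).
#'
#' @param mean,sd the statistics.
#' @param digits decimals to print.
#' @return a character scalar such as `"-0.12 ± 0.23"`.
#' @examples
#' format_mean_sd(-0.1234, 0.2293)
#' @export
format_mean_sd <- function(mean, sd, digits = 2) {
  sprintf("%.*f ± %.*f", digits, mean, digits, sd)
}

#' Format a p-value for table display
#'
#' Three decimals with a display floor: p below 0.0005 prints as `"0.000"`
#' (stored values keep full precision). Values below `alpha` are starred.
#'
#' @param p p-value(s).
#' @param alpha optional significance level; when given, `p < alpha` gets a
#'   trailing `" *"`.
#' @return character vector.
#' @examples
#' format_p(4e-6)          # "0.000"
#' format_p(0.008, 0.05)   # "0.008 *"
#' @export
format_p <- function(p, alpha = NULL) {
  out <- sprintf("%.3f", p)
  if (!is.null(alpha)) out <- ifelse(p < alpha, paste(out, "*"), out)
  out
}

# internal: features present in a table, in canonical order
feature_columns <- function(table) {
  intersect(c("mean_scl_uS", "max_scr_amp_uS", "scr_count",
              "sto2_decrease_pct", "vas_norm_pct"), names(table))
}

# display names for rendered tables
feature_label <- function(f) {
  c(mean_scl_uS = "Mean SCL [uS]",
    max_scr_amp_uS = "Max amplitude [uS]",
    scr_count = "SCR counts",
    sto2_decrease_pct = "Decrease in StO2 [%]",
    vas_norm_pct = "Normalized VAS [%]")[[f]]
}

#' Summarize a cohort feature table
#'
#' Produces the four summary tables of a cuff-pressure analysis:
#' per-condition descriptives (`mean ± SD` cells), the RM-ANOVA table, the
#' post hoc paired-t table (with `*` marking `p < alpha`), and the Pearson
#' correlation table against normalized VAS — plus per-feature assumption
#' checks and a rendered Markdown report.
#'
#' Inference columns are the physiological features (`mean_scl_uS`,
#' `max_scr_amp_uS`, `scr_count`, and `sto2_decrease_pct` when present);
#' normalized VAS enters the descriptives and is the correlation target.
#'
#' @param table a feature table from [build_feature_table()].
#' @param alpha significance level.
#' @param correction multiplicity correction for the paired tests.
#' @return an object of class `cohort_summary`: `descriptives`, `anova`,
#'   `pairwise`, `correlation`, `assumptions`, and `report` (character,
#'   Markdown).
#' @export
summarize_cohort <- function(table, alpha = 0.05,
                             correction = c("none", "holm", "bonferroni")) {
  correction <- match.arg(correction)
  if (!is.data.frame(table) || !nrow(table))
    stopf("parameter_error", "table must be a non-empty data.frame")
  feats <- feature_columns(table)
  infer <- setdiff(feats, "vas_norm_pct")
  pressures <- sort(unique(table$pressure_kPa))

  descr <- do.call(rbind, lapply(pressures, function(p) {
    rows <- table[table$pressure_kPa == p, , drop = FALSE]
    cells <- vapply(feats, function(f) {
      dg <- if (f == "scr_count") 1 else 2
      format_mean_sd(mean(rows[[f]]), sd(rows[[f]]), digits = dg)
    }, character(1))
    df <- data.frame(pressure_kPa = p)
    for (f in feats) df[[f]] <- cells[[f]]
    df
  }))

  anova_list <- lapply(infer, function(f) rm_anova(table, f))
  anova_df <- do.call(rbind, lapply(anova_list, function(a)
    data.frame(feature = a$feature, f_value = a$f_value, df_num = a$df_num,
               df_den = a$df_den, p_value = a$p_value,
               gg_epsilon = a$gg_epsilon, p_value_gg = a$p_value_gg)))

  pairwise <- if (length(pressures) >= 2)
    do.call(rbind, lapply(infer, function(f)
      paired_ttests(table, f, correction = correction, alpha = alpha)))
  else NULL

  corr <- if (!is.null(table$vas_norm_pct))
    do.call(rbind, lapply(infer, function(f) {
      ct <- pearson_vs_vas(table, f)
      data.frame(feature = ct$feature, r = ct$r, n = ct$n,
                 p_value = ct$p_value)
    }))
  else NULL

  assumptions <- lapply(infer, function(f) check_assumptions(table, f, alpha))
  names(assumptions) <- infer

  out <- structure(list(descriptives = descr, anova = anova_df,
                        pairwise = pairwise, correlation = corr,
                        assumptions = assumptions, alpha = alpha,
                        correction = correction),
                   class = "cohort_summary")
  out$report <- render_report(out)
  out
}

# internal: pipe-table helper
md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a cohort summary as Markdown
#'
#' @param summary a [summarize_cohort()] result.
#' @return a character scalar of Markdown.
#' @export
render_report <- function(summary) {
  if (!inherits(summary, "cohort_summary"))
    stopf("parameter_error", "summary must be a cohort_summary")
  a <- summary$alpha
  parts <- "# Cuff-pressure discomfort analysis\n"

  d <- summary$descriptives
  names(d) <- c("Pressure [kPa]",
                vapply(names(d)[-1], feature_label, character(1)))
  parts <- c(parts, "## Descriptives (mean ± SD per condition)\n",
             md_table(d), "")

  an <- summary$anova
  at <- data.frame(Feature = vapply(an$feature, feature_label, character(1)),
                   `F-value` = sprintf("%.3f", an$f_value),
                   df = sprintf("(%d, %d)", an$df_num, an$df_den),
                   `p-value` = format_p(an$p_value, a),
                   `GG eps` = sprintf("%.3f", an$gg_epsilon),
                   `p (GG)` = format_p(an$p_value_gg, a),
                   check.names = FALSE)
  parts <- c(parts, "## Repeated-measures ANOVA\n", md_table(at), "")

  if (!is.null(summary$pairwise)) {
    pw <- summary$pairwise
    groups <- unique(pw[, c("pressure_a", "pressure_b")])
    pt <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      sel <- pw$pressure_a == groups$pressure_a[i] &
        pw$pressure_b == groups$pressure_b[i]
      row <- data.frame(Group = sprintf("%g kPa vs. %g kPa",
                                        groups$pressure_a[i],
                                        groups$pressure_b[i]))
      for (f in unique(pw$feature[sel]))
        row[[feature_label(f)]] <-
          format_p(pw$p_adjusted[sel & pw$feature == f], a)
      row
    }))
    parts <- c(parts,
               sprintf("## Post hoc paired t-tests (correction: %s)\n",
                       summary$correction),
               md_table(pt), "", sprintf("`*`: p < %g.", a), "")
  }

  if (!is.null(summary$correlation)) {
    co <- summary$correlation
    ct <- data.frame(Feature = vapply(co$feature, feature_label, character(1)),
                     r = sprintf("%.2f", co$r), n = co$n,
                     `p-value` = format_p(co$p_value, a), check.names = FALSE)
    parts <- c(parts, "## Pearson correlation vs. normalized VAS\n",
               md_table(ct), "")
  }

  asum <- do.call(rbind, lapply(summary$assumptions, function(x)
    data.frame(Feature = feature_label(x$feature),
               `Mauchly W` = sprintf("%.3f", x$mauchly_W),
               `p (sphericity)` = if (is.na(x$mauchly_p)) "-" else
                 format_p(x$mauchly_p),
               `min Shapiro p` = format_p(min(x$normality$p_value)),
               check.names = FALSE)))
  parts <- c(parts, "## Assumption checks\n", md_table(asum), "")

  paste(parts, collapse = "\n")
}
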