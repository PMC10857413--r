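test_that("RM ANOVA matches the brute-force sums-of-squares oracle", {
  for (seed in 1:30) {
    n <- sample(4:12, 1)
    tab <- random_feature_table(n, seed = seed)
    res <- rm_anova(tab, "value")
    wide <- matrix(tab$value, n, 3, byrow = TRUE)
    orc <- oracle_rm_anova(wide)
    expect_equal(res$f_value, orc$f, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
    expect_identical(c(res$df_num, res$df_den), c(orc$df1, orc$df2))
    expect_equal(res$gg_epsilon, oracle_gg_epsilon(wide), tolerance = 1e-10)
    expect_gt(res$gg_epsilon, 1 / 2) # > 1/(k-1) for k = 3
    expect_lte(res$gg_epsilon, 1 + 1e-12)
  }
})

test_that("RM ANOVA agrees with car::Anova on F, epsilon and Mauchly", {
  tab <- random_feature_table(10, seed = 99)
  res <- rm_anova(tab, "value")
  chk <- check_assumptions(tab, "value")
  wide <- matrix(tab$value, 10, 3, byrow = TRUE)
  idata <- data.frame(cond = factor(1:3))
  ca <- car::Anova(lm(wide ~ 1), idata = idata, idesign = ~cond, type = 3)
  s <- suppressWarnings(summary(ca)) # car notes HF eps > 1; HF is unused here
  expect_equal(res$f_value, s$univariate.tests["cond", "F value"],
               tolerance = 1e-10)
  expect_equal(res$gg_epsilon, s$pval.adjustments["cond", "GG eps"],
               tolerance = 1e-10)
  expect_equal(res$p_value_gg, s$pval.adjustments["cond", "Pr(>F[GG])"],
               tolerance = 1e-10)
  expect_equal(chk$mauchly_W, s$sphericity.tests["cond", "Test statistic"],
               tolerance = 1e-10)
  expect_equal(chk$mauchly_p, s$sphericity.tests["cond", "p-value"],
               tolerance = 1e-10)
})

test_that("degenerate designs are handled per contract", {
  # identical values across conditions, subjects differ -> F = 0, p = 1
  tab <- data.frame(subject = rep(c("a", "b", "c"), each = 3),
                    pressure_kPa = rep(c(10, 20, 30), 3),
                    value = rep(c(1, 5, 9), each = 3))
  res <- rm_anova(tab, "value")
  expect_equal(res$f_value, 0)
  expect_equal(res$p_value, 1)

  # condition effect with zero interaction MS -> degenerate error
  tab2 <- tab
  tab2$value <- rep(c(1, 2, 3), 3)
  expect_error(rm_anova(tab2, "value"), class = "degenerate_data_error")

  # incomplete design
  expect_error(rm_anova(tab[-1, ], "value"), class = "design_error")
})

test_that("for two conditions, F equals the squared paired t", {
  for (seed in 1:10) {
    tab <- random_feature_table(8, k = 2, seed = 200 + seed)
    f <- rm_anova(tab, "value")$f_value
    t2 <- paired_ttests(tab, "value")$t_value^2
    expect_equal(f, t2, tolerance = 1e-9)
  }
})

test_that("paired t-tests match the closed form and the oracle", {
  # differences (1, 2, 3): t = 2 / (1/sqrt(3)), p = 2 P(T_2 < -t)
  tab <- data.frame(subject = rep(c("a", "b", "c"), each = 2),
                    pressure_kPa = rep(c(10, 20), 3),
                    value = c(0, 1, 0, 2, 0, 3))
  res <- paired_ttests(tab, "value")
  expect_equal(res$t_value, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$t_value, 3.4641, tolerance = 1e-4)
  expect_equal(res$p_value, 2 * pt(-sqrt(12), 2), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  for (seed in 1:10) {
    tab <- random_feature_table(9, seed = 300 + seed)
    res <- paired_ttests(tab, "value")
    wide <- matrix(tab$value, 9, 3, byrow = TRUE)
    combos <- list(c(1, 2), c(1, 3), c(2, 3))
    for (i in seq_along(combos)) {
      orc <- oracle_paired_t(wide[, combos[[i]][1]], wide[, combos[[i]][2]])
      expect_equal(res$t_value[i], orc$t, tolerance = 1e-10)
      expect_equal(res$p_value[i], orc$p, tolerance = 1e-10)
    }
  }
})

test_that("paired t-tests report all pressure pairs with significance flags", {
  tab <- random_feature_table(13, seed = 7)
  tab$value <- tab$value + tab$pressure_kPa / 12 # induce an effect
  res <- paired_ttests(tab, "value")
  expect_equal(res$pressure_a, c(10, 10, 20))
  expect_equal(res$pressure_b, c(20, 30, 30))
  expect_type(res$significant, "logical")
  expect_equal(res$significant, res$p_value < 0.05)
  # corrections never make p smaller
  holm <- paired_ttests(tab, "value", correction = "holm")
  expect_true(all(holm$p_adjusted >= res$p_value - 1e-15))
})

test_that("identical paired vectors give t = 0, p = 1; constant shifts error", {
  tab <- data.frame(subject = rep(c("a", "b", "c"), each = 2),
                    pressure_kPa = rep(c(10, 20), 3),
                    value = rep(c(2, 2), 3))
  res <- paired_ttests(tab, "value")
  expect_equal(res$t_value, 0)
  expect_equal(res$p_value, 1)
  tab$value <- rep(c(2, 3), 3) # constant non-zero difference
  expect_error(paired_ttests(tab, "value"), class = "degenerate_data_error")
})

test_that("Pearson correlation matches the definitional oracle", {
  tab <- data.frame(feature = 1:10, vas_norm_pct = 2 * (1:10) + 1)
  expect_equal(pearson_vs_vas(tab, "feature")$r, 1, tolerance = 1e-12)
  tab$vas_norm_pct <- -(1:10)
  expect_equal(pearson_vs_vas(tab, "feature")$r, -1, tolerance = 1e-12)

  set.seed(17)
  for (i in 1:10) {
    tab <- data.frame(feature = rnorm(10), vas_norm_pct = rnorm(10))
    res <- pearson_vs_vas(tab, "feature")
    expect_equal(res$r, oracle_pearson(tab$feature, tab$vas_norm_pct),
                 tolerance = 1e-12)
    expect_equal(res$n, 10)
  }
  expect_error(pearson_vs_vas(data.frame(feature = rep(1, 5),
                                         vas_norm_pct = rnorm(5)),
                              "feature"),
               class = "degenerate_data_error")
})

test_that("two conditions satisfy sphericity trivially", {
  tab <- random_feature_table(6, k = 2, seed = 55)
  rep <- check_assumptions(tab, "value")
  expect_equal(rep$mauchly_W, 1)
  expect_true(rep$sphericity_ok)
  expect_equal(nrow(rep$normality), 2)
})

test_that("Mauchly's test is calibrated under compound symmetry", {
  # spherical data: rejection rate should sit near the nominal 5%
  reject <- vapply(1:500, function(r) {
    set.seed(10000 + r)
    wide <- matrix(rnorm(200 * 3), 200, 3) + rnorm(200, 0, 1)
    tab <- data.frame(subject = rep(sprintf("S%03d", 1:200), each = 3),
                      pressure_kPa = rep(c(10, 20, 30), 200),
                      value = as.vector(t(wide)))
    check_assumptions(tab, "value")$mauchly_p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("Mauchly's test detects strong heteroscedasticity", {
  reject <- vapply(1:200, function(r) {
    set.seed(20000 + r)
    # AR-like structure with strongly unequal variances
    e1 <- rnorm(40); e2 <- 0.8 * e1 + rnorm(40, 0, 2); e3 <- 0.8 * e2 + rnorm(40, 0, 3)
    tab <- data.frame(subject = rep(sprintf("S%03d", 1:40), each = 3),
                      pressure_kPa = rep(c(10, 20, 30), 40),
                      value = as.vector(rbind(e1, e2, e3)))
    check_assumptions(tab, "value")$mauchly_p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.5)
})

test_that("summary tables use the published formatting conventions", {
  expect_equal(format_mean_sd(-0.12, 0.23), "-0.12 ± 0.23")
  expect_equal(format_mean_sd(5.3, 3.8, digits = 1), "5.3 ± 3.8")
  expect_equal(format_p(4e-6), "0.000")
  expect_equal(format_p(0.008, alpha = 0.05), "0.008 *")
  expect_equal(format_p(0.086, alpha = 0.05), "0.086")

  # a feature column with mean -0.12 and SD 0.23 renders as "-0.12 ± 0.23"
  tab <- data.frame(subject = rep(c("a", "b", "c"), each = 3),
                    pressure_kPa = rep(c(10, 20, 30), 3),
                    mean_scl_uS = c(-0.35, 1, 2, -0.12, 2, 3, 0.11, 3, 4))
  tab$mean_scl_uS[tab$pressure_kPa != 10] <- rnorm(6)
  tab$mean_scl_uS[tab$pressure_kPa == 10] <- c(-0.35, -0.12, 0.11)
  sm <- summarize_cohort(tab)
  expect_equal(sm$descriptives$mean_scl_uS[1], "-0.12 ± 0.23")
  expect_match(sm$report, "Mean SCL")
})

test_that("reports omit the pairwise table when there are no pairs", {
  tab <- random_feature_table(6, seed = 61)
  names(tab)[3] <- "mean_scl_uS"
  sm <- summarize_cohort(tab)
  expect_match(sm$report, "Post hoc")
  sm$pairwise <- NULL
  txt <- render_report(sm)
  expect_false(grepl("Post hoc", txt))
  expect_match(txt, "Repeated-measures ANOVA")
})
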