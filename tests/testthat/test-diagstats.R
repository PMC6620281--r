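test_that("Kruskal-Wallis: degenerate case, hand value, rank invariance", {
  same <- list(rep(2, 3), rep(2, 4), rep(2, 3))
  kw0 <- kruskal_wallis(same)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  set.seed(1)
  g <- list(rnorm(6), rnorm(7, 1), rnorm(5, 2))
  kw1 <- kruskal_wallis(g)
  kw2 <- kruskal_wallis(lapply(g, function(x) exp(3 * x))) # monotone transform
  expect_equal(kw2$statistic, kw1$statistic)
  expect_equal(kw2$p_value, kw1$p_value)

  expect_error(kruskal_wallis(list(1:3, 4:6)), class = "lsn_parameter_error")
})

test_that("Mann-Whitney: exact enumeration, symmetry, approximation quality", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(mw$exact)
  expect_equal(mw$p_value, oracle_mw_exact(c(1, 2), c(3, 4)), tolerance = 1e-12)

  # exact branch matches enumeration on random small samples
  set.seed(2)
  for (i in 1:20) {
    a <- round(rnorm(3 + i %% 3, 0, 10), 3)
    b <- round(rnorm(3 + (i + 1) %% 3, 1, 10), 3)
    res <- mann_whitney(a, b)
    expect_equal(res$p_value, oracle_mw_exact(a, b), tolerance = 1e-12)
  }

  expect_equal(mann_whitney(c(5, 1, 7), c(2, 9, 4))$p_value,
               mann_whitney(c(2, 9, 4), c(5, 1, 7))$p_value)

  # normal-approximation branch (n = 7 + 6 > enumeration cutoff) agrees with
  # the enumeration oracle within 0.02 over 100 random datasets
  set.seed(3)
  for (i in 1:100) {
    a <- rnorm(7); b <- rnorm(6, 0.5)
    res <- mann_whitney(a, b)
    expect_false(res$exact)
    expect_lt(abs(res$p_value - oracle_mw_exact(a, b)), 0.02)
  }
})

test_that("Wilcoxon signed-rank: ties to enumeration, conventions", {
  expect_equal(wilcoxon_signed(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  w <- wilcoxon_signed(c(2, 4, 6), c(1, 2, 3))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.25, tolerance = 1e-12)
  expect_equal(w$p_value, oracle_wsr_exact(c(2, 4, 6), c(1, 2, 3)),
               tolerance = 1e-12)

  set.seed(4)
  for (i in 1:20) {
    a <- round(rnorm(4 + i %% 3, 0, 5), 3)
    b <- round(rnorm(length(a), 0.5, 5), 3)
    res <- wilcoxon_signed(a, b)
    if (res$exact) {
      expect_equal(res$p_value, oracle_wsr_exact(a, b), tolerance = 1e-12)
    } else {
      # tied |differences| fall back to the normal approximation
      expect_lt(abs(res$p_value - oracle_wsr_exact(a, b)), 0.05)
    }
    expect_equal(res$p_value, wilcoxon_signed(b, a)$p_value)
  }
})

test_that("coefficient of variation", {
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2 * 100,
               tolerance = 1e-12)
  expect_equal(round(mean(c(7, 13, 14)), 1), 11.3)
  expect_error(coefficient_of_variation(c(-1, 1)), class = "lsn_domain_error")
})

test_that("ICC(2,1): perfect agreement, hand-ANOVA oracle, labels", {
  m <- cbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  r <- icc_agreement(m)
  expect_equal(r$icc, 1)
  expect_equal(unname(r$ci95["upper"]), 1, tolerance = 1e-9)

  # 6x2 toy table: Shrout-Fleiss formula from hand-computed mean squares
  set.seed(5)
  tab <- cbind(rnorm(6, 10, 2), rnorm(6, 10.5, 2))
  n <- 6; k <- 2
  grand <- mean(tab)
  MSR <- k * sum((rowMeans(tab) - grand)^2) / (n - 1)
  MSC <- n * sum((colMeans(tab) - grand)^2) / (k - 1)
  MSE <- (sum((tab - grand)^2) - (n - 1) * MSR - (k - 1) * MSC) /
    ((n - 1) * (k - 1))
  icc_hand <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  expect_equal(icc_agreement(tab)$icc, icc_hand, tolerance = 1e-12)

  expect_identical(icc_label(0.713), "good")
  expect_identical(icc_label(0.39), "poor")
  expect_identical(icc_label(0.85), "excellent")

  expect_error(icc_agreement(matrix(rep(2, 10), 5, 2)),
               class = "lsn_domain_error")
  expect_error(icc_agreement(matrix(rnorm(8), 4, 2)),
               class = "lsn_parameter_error")
})

test_that("ROC: perfect separation, U identity, null calibration", {
  rr <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(rr$auc, 1)
  expect_gte(rr$cutoff, 2)
  expect_lt(rr$cutoff, 3)
  expect_equal(rr$sensitivity, 100)
  expect_equal(rr$specificity, 100)

  # AUC = U / (n1 n0), checked on 100 random datasets
  set.seed(6)
  for (i in 1:100) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    pos <- rnorm(n1, 0.5); neg <- rnorm(n0)
    auc <- roc_analysis(c(pos, neg), c(rep(1, n1), rep(0, n0)))$auc
    U <- mann_whitney(pos, neg)$statistic
    expect_equal(auc, U / (n1 * n0), tolerance = 1e-12)
  }

  # labels independent of scores: AUC within 0.5 +/- 0.1 for >= 95/100 seeds
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    sc <- rnorm(200); lb <- rbinom(200, 1, 0.5)
    if (length(unique(lb)) < 2) next
    a <- roc_analysis(sc, lb)$auc
    if (abs(a - 0.5) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 95)

  # monotone rescaling leaves the AUC unchanged
  set.seed(7)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.5)
  expect_equal(roc_analysis(exp(sc), lb)$auc, roc_analysis(sc, lb)$auc)

  expect_error(roc_analysis(1:5, rep(1, 5)), class = "lsn_domain_error")
})

test_that("confusion_stats: published contingency rows and edge cases", {
  r1 <- confusion_stats(tp = 21, fp = 3, tn = 4, fn = 2)
  expect_equal(round(r1$sensitivity, 1), 91.3)
  expect_equal(round(r1$specificity, 1), 57.1)
  expect_equal(round(r1$ppv, 1), 87.5)
  expect_equal(round(r1$npv, 1), 66.7)

  r2 <- confusion_stats(tp = 10, fp = 3, tn = 8, fn = 2)
  expect_equal(round(r2$sensitivity, 1), 83.3)
  expect_equal(round(r2$specificity, 1), 72.7)
  expect_equal(round(r2$ppv, 1), 76.9)
  expect_equal(round(r2$npv, 1), 80.0)

  r3 <- confusion_stats(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(unlist(r3), c(sensitivity = 100, specificity = 100,
                             ppv = 100, npv = 100))
  expect_true(is.na(confusion_stats(tp = 0, fp = 0, tn = 5, fn = 2)$ppv))
  expect_error(confusion_stats(-1, 0, 1, 1), class = "lsn_parameter_error")
})

test_that("cohort report: summaries, simulated power, formatting", {
  # constant NC stratum
  tab <- cohort_table(
    subject_id = sprintf("s%02d", 1:10),
    group = c(rep("NC", 4), rep("SS", 3), rep("NASH", 3)),
    fibrosis_grade = c(rep("F0", 4), rep("F1", 3), c("F2", "F2", "F3")),
    lsn_score = c(rep(1.30, 4), 1.5, 1.6, 1.55, 1.7, 1.8, 1.75))
  rep1 <- cohort_report(tab)
  expect_equal(unname(rep1$group_stats["NC", "mean"]), 1.30)
  expect_equal(unname(rep1$group_stats["NC", "sd"]), 0)
  expect_equal(unname(rep1$group_stats["NC", "cv"]), 0)
  md <- render_report_markdown(rep1)
  expect_true(any(grepl("\\d+\\.\\d \\(\\d+/\\d+\\)", md))) # pct (raw/raw)

  # simulated cohorts at the reported group effect sizes: Kruskal-Wallis
  # p < 0.05 in at least 80 of 100 seeds
  sig <- 0
  for (s in 1:100) {
    set.seed(s)
    scores <- c(rnorm(7, 1.30, 0.09), rnorm(12, 1.54, 0.21), rnorm(11, 1.59, 0.23))
    kw <- kruskal_wallis(list(scores[1:7], scores[8:19], scores[20:30]))
    if (kw$p_value < 0.05) sig <- sig + 1
  }
  expect_gte(sig, 80)

  # Holm flag off by default, on-demand adjustment
  expect_null(rep1$pairwise_groups$p_adjusted)
  rep2 <- cohort_report(tab, holm = TRUE)
  expect_equal(rep2$pairwise_groups$p_adjusted,
               p.adjust(rep2$pairwise_groups$p_value, "holm"))
})

test_that("NAS aggregation is the sum of component scores", {
  expect_equal(nas_score(1.3, 1.0, 1.3), 3.6)
  expect_equal(nas_score(0, 0, 0), 0)
})
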