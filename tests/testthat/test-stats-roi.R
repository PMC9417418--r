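test_that("ROI averaging is an unweighted mean, order-invariant", {
  feats <- data.frame(channel = c("E70", "E75", "E36", "E104"),
                      sso_rate = c(10, 20, 5, 7))
  lay <- roi_layout(occipital = c("E70", "E75"),
                    sensorimotor = c("E36", "E104"))
  ra <- roi_average(feats, lay)
  expect_equal(ra$sso_rate[ra$roi == "occipital"], 15)
  expect_equal(ra$n_channels, c(2, 2))
  ra2 <- roi_average(feats[4:1, ], lay)
  expect_equal(ra, ra2)
  # emptied ROI is NA-flagged
  ra3 <- roi_average(feats[1:2, ], lay)
  expect_true(is.na(ra3$sso_rate[ra3$roi == "sensorimotor"]))
  expect_error(roi_layout(a = "E1", b = "E1"), "disjoint")
})

test_that("condition changes are MD-minus-control and antisymmetric", {
  tab <- data.frame(subject = rep(c("s1", "s2"), each = 2),
                    condition = rep(c("MDnight", "Cnight"), 2),
                    sso_rate = c(12, 10, 8, 8))
  ch <- condition_change(tab)
  expect_equal(ch$d_sso_rate, c(2, 0))
  tab_sw <- tab
  tab_sw$condition <- ifelse(tab$condition == "MDnight", "Cnight", "MDnight")
  expect_equal(condition_change(tab_sw)$d_sso_rate, -ch$d_sso_rate)
  # missing night drops the subject with a message
  expect_message(ch2 <- condition_change(tab[-4, ]), "missing night")
  expect_equal(ch2$subject, "s1")
})

test_that("spearman matches brute-force midranks and monotone invariance", {
  expect_equal(spearman_test(1:6, (1:6)^2)$statistic, 1)
  set.seed(41)
  for (i in 1:20) {
    x <- sample(1:5, 8, replace = TRUE)   # ties likely
    y <- rnorm(8)
    r <- spearman_test(x, y)$statistic
    expect_equal(r, oracle_spearman_rho(x, y), tolerance = 1e-12)
    # strictly monotone transforms leave rho untouched
    expect_equal(spearman_test(exp(x), y)$statistic, r)
    expect_equal(spearman_test(x, qnorm(pnorm(y)))$statistic, r)
  }
  expect_error(spearman_test(rep(1, 6), 1:6), "constant")
  expect_error(spearman_test(1:3, 1:3), "pairs")
})

test_that("BH adjustment reproduces the hand step-up computation", {
  res <- fdr_bh(c(0.009, 0.012, 0.03, 0.4))
  expect_equal(res$p_fdr, c(0.024, 0.024, 0.04, 0.4))
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  # single p: adjusted equals raw; all-equal p stay put
  expect_equal(fdr_bh(0.03)$p_fdr, 0.03)
  expect_equal(fdr_bh(rep(0.2, 5))$p_fdr, rep(0.2, 5))
  # random vectors match the independent step-up oracle, monotone in p
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(fdr_bh(p)$p_fdr, oracle_bh(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(fdr_bh(p)$p_fdr[o]) >= -1e-12))
  }
  expect_error(fdr_bh(numeric()), "empty")
  expect_error(fdr_bh(c(0.1, 1.2)), "0,1")
})

test_that("wilcoxon signed-rank matches enumeration and detects shifts", {
  x <- c(10.2, 9.8, 11.1, 10.6, 9.9, 10.8)
  y <- c(9.1, 10.0, 9.8, 9.9, 9.5, 10.1)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$statistic, oracle_wilcoxon_v(x, y))
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(wilcoxon_signed_rank(a, b)$statistic,
                 oracle_wilcoxon_v(a, b))
  }
  # y = x: degenerate, p = 1, no rejection
  res <- wilcoxon_signed_rank(x, x)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  # large constant shift at n = 10 is significant
  a <- rnorm(10)
  expect_lt(wilcoxon_signed_rank(a, a + 5)$p, 0.05)
})

test_that("one-sample t against 1 matches the closed form", {
  x <- c(0.8, 0.9, 1.1, 0.7)
  res <- t_test_vs(x, mu = 1)
  tt <- (mean(x) - 1) / (sd(x) / sqrt(4))
  expect_equal(res$statistic, tt)
  expect_equal(res$p, 2 * pt(abs(tt), 3, lower.tail = FALSE))
  expect_equal(res$effect, abs(mean(x) - 1) / sd(x))
  expect_equal(res$df, 3)
  # all-ones sample: degenerate no-change result
  res <- t_test_vs(rep(1, 5), mu = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$effect, 0)
  expect_true(res$degenerate)
  expect_error(t_test_vs(rep(2, 5), mu = 1), "variance")
  # paired variant equals one-sample on differences
  y <- c(0.9, 0.8, 1.0, 0.9)
  expect_equal(t_test_vs(x, y)$statistic,
               t_test_vs(x - y + 1, mu = 1)$statistic)
})

test_that("repeated-measures ANOVA matches the SS decomposition oracle", {
  # identical values across levels: F = 0
  d0 <- expand.grid(subject = paste0("s", 1:4), time = paste0("t", 1:3))
  d0$y <- rep(c(3, 5, 4, 6), 3)
  a0 <- rm_anova(d0, "y", "subject", "time")
  expect_equal(a0$F, 0)
  # toy 3 x 5 table against hand sums of squares
  set.seed(55)
  d <- expand.grid(subject = paste0("s", 1:3), time = paste0("t", 1:5))
  d$y <- rnorm(15, mean = as.integer(d$time))
  a <- rm_anova(d, "y", "subject", "time")
  orc <- oracle_rm_ss(d$y, d$subject, d$time)
  expect_equal(a$F, orc$F, tolerance = 1e-9)
  expect_equal(a$df1, 4)
  expect_equal(a$df2, 8)
  expect_equal(a$pes, orc$ss_level / (orc$ss_level + orc$ss_err),
               tolerance = 1e-9)
  # conservation: decomposed SS sum to the total
  expect_equal(orc$ss_level + orc$ss_subj + orc$ss_err, orc$ss_total)
  # incomplete subject dropped with message
  expect_message(a2 <- rm_anova(d[-1, ], "y", "subject", "time"), "dropping")
  # 2 x 2 within design reports the interaction
  d2 <- expand.grid(subject = paste0("s", 1:6), time = c("before", "after"),
                    condition = c("MDnight", "MDmorn"))
  set.seed(66)
  d2$y <- rnorm(24) + ifelse(d2$time == "after" & d2$condition == "MDmorn",
                             1.5, 0)
  a2 <- rm_anova(d2, "y", "subject", c("time", "condition"))
  expect_true("time:condition" %in% a2$effect)
  expect_equal(nrow(a2), 3)
  expect_true(all(a2$pes >= 0 & a2$pes <= 1))
})

test_that("cohort correlation stage recovers rho and controls the FDR", {
  co <- generate_cohort(15, target_rho = -0.9, noise_sd = 0, seed = 10)
  res <- correlate_features(co)
  expect_equal(nrow(res), 8)
  expect_true(all(res$p_fdr >= res$p))
  coupled <- paste0("d_", attr(co, "coupled"))
  got <- res$statistic[res$comparison %in% paste("di_before vs", coupled)]
  expect_true(all(got < -0.5))
})
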