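test_that("eclosion rate, fold decrease and host fractions are ratios", {
  expect_equal(eclosion_rate(data.frame(n_larvae = 100, n_adults = 0)), 0)
  expect_equal(eclosion_rate(data.frame(n_larvae = 48, n_adults = 48)), 100)
  expect_equal(eclosion_rate(data.frame(n_larvae = 50, n_adults = 6)), 12)
  expect_error(eclosion_rate(data.frame(n_larvae = 0, n_adults = 0)), ">= 1")
  expect_equal(fold_decrease(46, 5), 9.2)
  expect_equal(fold_decrease(33, 33), 1)
  expect_equal(fold_decrease(14, 7), 2)
  expect_error(fold_decrease(46, 0), "> 0")
  expect_equal(tumor_bearing_fraction(0, 30), 0)
  expect_equal(tumor_bearing_fraction(3, 100), 3)
  expect_equal(tumor_bearing_fraction(6, 10), 60)
  expect_error(tumor_bearing_fraction(1, 0), ">= 1")
})

test_that("condition summaries report mean and sample SD", {
  s1 <- summarize_condition(5, "x")
  expect_equal(c(s1$mean, s1$sd, s1$n), c(5, 0, 1))
  s2 <- summarize_condition(c(2, 4, 6), "x")
  expect_equal(c(s2$mean, s2$sd), c(4, 2))
  expect_equal(summarize_condition(rep(7, 5), "x")$sd, 0)
  expect_error(summarize_condition(numeric(0), "x"), "no values")
})

test_that("Kruskal-Wallis reproduces the rank-sum hand calculation", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(kw$statistic, 3.857, tolerance = 5e-4)
  # permutation of group order leaves H unchanged
  kw2 <- kruskal_wallis(list(b = c(4, 5, 6), a = c(1, 2, 3)))
  expect_equal(kw2$statistic, kw$statistic)
  # degenerate all-identical data
  kw3 <- kruskal_wallis(list(a = c(1, 1), b = c(1, 1)))
  expect_true(kw3$degenerate)
  expect_equal(kw3$p.value, 1)
})

test_that("Kruskal-Wallis holds its nominal type-I error", {
  set.seed(10)
  n_sim <- 1500
  rej <- vapply(seq_len(n_sim), function(i) {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    kruskal_wallis(g)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Dunn's z and Bonferroni adjustment match the hand formulas", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- dunn_posthoc(g, mode = "all-pairs")
  # hand calculation: mean ranks 2, 5, 8; sigma2 = 9*10/12 = 7.5 (no ties)
  z_ab <- (2 - 5) / sqrt(7.5 * (2 / 3))
  expect_equal(res$comparisons$statistic[1], z_ab, tolerance = 1e-10)
  expect_equal(res$comparisons$p.value, 2 * pnorm(-abs(res$comparisons$statistic)))
  expect_equal(res$comparisons$p.adjusted,
               pmin(1, 3 * res$comparisons$p.value))
  expect_equal(round(res$comparisons$statistic[1], 3), -1.342)
  # identical equal-size groups: z = 0, adjusted p = 1
  same <- dunn_posthoc(list(a = c(1, 2), b = c(1, 2)), mode = "all-pairs")
  expect_equal(same$comparisons$statistic, 0)
  expect_equal(same$comparisons$p.adjusted, 1)
  # vs-control yields k - 1 comparisons
  vs <- dunn_posthoc(g, mode = "vs-control", control = "a")
  expect_equal(nrow(vs$comparisons), 2)
  expect_true(all(vs$comparisons$group1 == "a"))
  expect_error(dunn_posthoc(g, mode = "vs-control", control = "zz"),
               "unknown control")
})

test_that("Dunn handles ties through the tie-corrected variance", {
  g <- list(a = c(1, 2, 2), b = c(2, 3, 4))
  res <- dunn_posthoc(g, mode = "all-pairs")
  pooled <- unlist(g)
  rk <- rank(pooled)
  ties <- table(pooled)
  sigma2 <- 6 * 7 / 12 - sum(ties^3 - ties) / (12 * 5)
  z <- (mean(rk[1:3]) - mean(rk[4:6])) / sqrt(sigma2 * (2 / 3))
  expect_equal(res$comparisons$statistic, z, tolerance = 1e-12)
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(11)
  g <- list(a = rlnorm(7), b = rlnorm(9, 0.5), c = rlnorm(5, 1))
  g_t <- lapply(g, function(x) log(x) * 3 + 2)
  expect_equal(kruskal_wallis(g)$statistic, kruskal_wallis(g_t)$statistic)
  expect_equal(dunn_posthoc(g)$comparisons$statistic,
               dunn_posthoc(g_t)$comparisons$statistic)
})

test_that("Dunnett comparisons agree with an independent implementation", {
  set.seed(12)
  g <- list(ctrl = rnorm(8), a = rnorm(10, 0.9), b = rnorm(6, -0.4),
            c = rnorm(9))
  res <- anova_dunnett(g, control = "ctrl", n_mc = 2e5)
  df <- data.frame(y = unlist(g),
                   g = factor(rep(names(g), lengths(g)), levels = names(g)))
  fit <- stats::aov(y ~ g, df)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(res$comparisons$statistic, unname(as.numeric(mc$test$tstat)),
               tolerance = 1e-8)
  expect_equal(res$comparisons$p.adjusted, unname(as.numeric(mc$test$pvalues)),
               tolerance = 0.01)
  # adjusted never below raw, monotone within the family
  expect_true(all(res$comparisons$p.adjusted >= res$comparisons$p.value))
  ord <- order(res$comparisons$p.value)
  expect_true(all(diff(res$comparisons$p.adjusted[ord]) >= -1e-12))
})

test_that("the two-group Dunnett reduces to the pooled t-test", {
  set.seed(13)
  g <- list(ctrl = rnorm(10), t = rnorm(10, 0.6))
  res <- anova_dunnett(g, control = "ctrl", n_mc = 2e5)
  tt <- stats::t.test(g$t, g$ctrl, var.equal = TRUE)
  expect_equal(res$comparisons$p.adjusted, tt$p.value, tolerance = 0.01)
  expect_equal(res$comparisons$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate ANOVA input is reported, not crashed", {
  g <- list(a = c(2, 2, 2), b = c(2, 2, 2), ctrl = c(2, 2, 2))
  res <- anova_dunnett(g, control = "ctrl")
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
  expect_true(all(res$comparisons$p.adjusted == 1))
  expect_error(anova_dunnett(list(a = 1:3, b = 1:3), control = "zz"),
               "missing")
})

test_that("significance stars follow the reported thresholds", {
  expect_equal(p_stars(c(5e-5, 5e-4, 5e-3, 0.03, 0.2)),
               c("****", "***", "**", "*", "ns"))
})
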